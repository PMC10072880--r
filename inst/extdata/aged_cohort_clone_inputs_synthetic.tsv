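tissue	n_snv	clonality_pct	G>A/C>T	T>C/A>G	G>T/C>A	G>C/C>G	T>A/A>T	T>G/A>C
kidney	5907	10.4	0.60	0.19	0.09	0.04	0.06	0.02
liver	4027	5.6	0.62	0.20	0.07	0.03	0.06	0.02
rpe_choroid	3132	3.0	0.58	0.23	0.08	0.04	0.05	0.02
hippocampus	2730	2.5	0.60	0.23	0.08	0.04	0.04	0.01
retina	2685	5.6	0.62	0.21	0.08	0.04	0.04	0.01
cerebellum	2237	2.5	0.52	0.21	0.15	0.07	0.04	0.01
muscle	1969	3.0	0.54	0.17	0.18	0.07	0.03	0.01
heart	1557	2.0	0.46	0.17	0.23	0.11	0.02	0.01
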