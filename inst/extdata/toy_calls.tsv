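sample_id	position	ref	alt	supporting_reads	depth	indel_length	note
k1	5170	C	T	5	10000	0	inside_oril
k1	2365	G	A	4	10000	0	inside_masked_repeat
k1	5159	G	T	3	10000	0	one_base_before_oril
k1	100	C	A	150	10000	0	vaf_above_cutoff
k1	200	G	A	100	10000	0	vaf_exactly_cutoff
k1	300	T	C	2	90	0	depth_below_cutoff
k1	400	G	A	6	10000	0	present_in_all_samples
k1	500	C	T	4	10000	0	present_in_two_of_three
k1	600	G	T	2	10000	0	numt_reads_dropped
k1	700	C	G	2	10000	0	numt_escore_tie
k1	800	T	ins16	3	10000	16	overlong_indel
k1	900	T	del2	1	10000	2	plain_indel
l1	400	G	A	5	9500	0	present_in_all_samples
l1	500	C	T	3	9500	0	present_in_two_of_three
h1	400	G	A	4	9800	0	present_in_all_samples
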