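read_id	subject	e_score	is_original
r1	chrM	1e-50	TRUE
r1	chr1_numt	1e-60	FALSE
r2	chrM	1e-50	TRUE
r2	chr1_numt	1e-60	FALSE
r3	chrM	1e-60	TRUE
r3	chr7_numt	1e-60	FALSE
r4	chrM	1e-60	TRUE
r4	chr7_numt	1e-60	FALSE
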