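class	acyl_carbons	double_bonds	adduct	reference_rt_min	rt_tolerance_min
PC	34	2	+H	7.0	0.1
PE	34	3	+H	6.45	0.1
DGDG	36	6	+NH4	8.35	0.1
SQDG	34	2	+NH4	6.1	0.1
DAG	34	2	+NH4	9.5	0.1
TAG	52	3	+NH4	15.15	0.1
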