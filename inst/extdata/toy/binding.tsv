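compound	kinase	value	measure
D1	EGFR	0.01	Kd_uM
D1	LYN	2	Kd_uM
D2	EGFR	0.5	Kd_uM
D2	CDK5 / p25	90	percent_inhibition
D3	LYN	0.1	Kd_uM
D3	MAP4K4	0.9	Kd_uM
D4	MAP4K4	99	percent_inhibition
D5	CDK5 / p25	5	Kd_uM
D5	LYN	80	percent_inhibition
D6	EGFR	86	percent_inhibition
D6	MAP4K4	1.0	Kd_uM
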