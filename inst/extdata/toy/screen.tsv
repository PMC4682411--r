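cell_line	D1	D2	D3	D4	D5	D6
CL1	0.05	0.5	8	GT_MAX	0.2	3
CL2	12		0.08	0.9	1	6
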