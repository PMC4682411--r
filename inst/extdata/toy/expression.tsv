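gene	CL1	CL2
EGFR	9.1	4.0
LYN	7.5	8.0
CDK5	6.0	6.5
GAPDH	12	12
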