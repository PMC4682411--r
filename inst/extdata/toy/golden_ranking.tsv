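cell_line	rank	kinase	raw_score	chi2_p	fisher_p	reported_p	fdr	significant	direction	expressed	n_inh_sens	n_inh_insens	n_noninh_sens	n_noninh_insens
CL1	1	EGFR	35	0.025347318677468304	0.1	0.1	0.4	TRUE	positive	expressed	3	0	0	2
CL1	2	CDK5/P25	10	0.36131042852617878	0.6	0.6	1	FALSE	positive	expressed	1	0	2	2
CL1	3	LYN	0	0.17090352023079752	1	1	1	FALSE	negative	expressed	0	1	3	1
CL1	4	MAP4K4	-10	0.025347318677468304	1	1	1	FALSE	negative	unmeasured	0	2	3	0
CL2	1	MAP4K4	30	0.045500263896358473	0.16666666666666666	0.16666666666666666	0.33333333333333331	TRUE	positive	unmeasured	2	0	0	2
CL2	2	LYN	20	0.24821307898992362	0.5	0.5	0.5	FALSE	positive	expressed	1	0	1	2
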