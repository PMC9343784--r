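contrast	category	n_hyper	n_hypo
SAL_SAL-vs-METH_SAL	Exons	34	37
SAL_SAL-vs-METH_SAL	Intergenic	440	316
SAL_SAL-vs-METH_SAL	Introns	432	268
SAL_SAL-vs-METH_SAL	Promoter	19	24
SAL_SAL-vs-METH_SAL	CpG islands	16	1
SAL_SAL-vs-SAL_METH	Exons	34	9
SAL_SAL-vs-SAL_METH	Intergenic	277	88
SAL_SAL-vs-SAL_METH	Introns	238	47
SAL_SAL-vs-SAL_METH	Promoter	16	1
SAL_SAL-vs-SAL_METH	CpG islands	16	0
METH_SAL-vs-METH_METH	Exons	49	21
METH_SAL-vs-METH_METH	Intergenic	333	174
METH_SAL-vs-METH_METH	Introns	310	134
METH_SAL-vs-METH_METH	Promoter	27	12
METH_SAL-vs-METH_METH	CpG islands	12	3
SAL_METH-vs-METH_METH	Exons	21	20
SAL_METH-vs-METH_METH	Intergenic	152	103
SAL_METH-vs-METH_METH	Introns	133	107
SAL_METH-vs-METH_METH	Promoter	15	11
SAL_METH-vs-METH_METH	CpG islands	4	3
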