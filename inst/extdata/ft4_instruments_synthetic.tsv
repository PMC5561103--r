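SNP	effect_allele	other_allele	eaf	beta	se	pval	n
rs7860634	A	G	0.269	0.051996	0.006	4.475e-18	17520
rs11726248	T	C	0.297	0.053092	0.006	8.852e-19	17520
rs11103377	G	A	0.613	0.049404	0.006	1.809e-16	17520
rs7694879	C	T	0.595	0.050164	0.006	6.239e-17	17520
rs113107469	A	G	0.307	0.041612	0.006	4.05e-12	17520
rs7045138	T	C	0.437	0.049039	0.006	3.005e-16	17520
rs9100001	G	A	0.705	0.052786	0.006	1.396e-18	17520
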