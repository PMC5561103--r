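SNP	effect_allele	other_allele	eaf	beta	se	pval	n
rs653178	A	G	0.539	0.147902	0.025	3.297e-09	18297
rs9200001	T	C	0.351	0.145774	0.025	5.511e-09	18297
rs9200002	G	A	0.775	0.139194	0.025	2.58e-08	18297
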