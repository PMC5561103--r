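SNP	effect_allele	other_allele	eaf	beta	se	pval	n
rs12410532	A	G	0.562	0.043267	0.006	5.55e-13	26420
rs28435578	T	C	0.589	0.049514	0.006	1.554e-16	26420
rs2046045	G	A	0.631	0.038606	0.006	1.241e-10	26420
rs6923866	C	T	0.169	0.0521	0.006	3.844e-18	26420
rs2396084	A	G	0.476	0.042638	0.006	1.192e-12	26420
rs3008034	T	C	0.601	0.04502	0.006	6.222e-14	26420
rs116552240	G	A	0.498	0.050982	0.006	1.945e-17	26420
rs17767742	C	T	0.757	0.049039	0.006	3.005e-16	26420
rs10799824	A	G	0.444	0.046476	0.006	9.486e-15	26420
rs10032216	T	C	0.758	0.0541	0.006	1.939e-19	26420
rs6885099	G	A	0.384	0.044538	0.006	1.146e-13	26420
rs11755845	C	T	0.55	0.054696	0.006	7.801e-20	26420
rs9472138	A	G	0.835	0.047774	0.006	1.687e-15	26420
rs753760	T	C	0.686	0.048	0.006	1.244e-15	26420
rs657152	G	A	0.413	0.055317	0.006	2.984e-20	26420
rs3813582	C	T	0.727	0.053329	0.006	6.211e-19	26420
rs13015993	A	G	0.814	0.048112	0.006	1.068e-15	26420
rs7568039	T	C	0.754	0.0431	0.006	6.804e-13	26420
rs2928167	G	A	0.492	0.052616	0.006	1.798e-18	26420
rs9000001	C	T	0.682	0.053126	0.006	8.415e-19	26420
rs9000002	A	G	0.753	0.04597	0.006	1.836e-14	26420
rs9000003	T	C	0.552	0.050414	0.006	4.375e-17	26420
rs9000004	G	A	0.849	0.040782	0.006	1.068e-11	26420
rs9000005	C	T	0.239	0.053092	0.006	8.852e-19	26420
rs9000006	A	G	0.584	0.054233	0.006	1.584e-19	26420
rs9000007	T	C	0.773	0.051229	0.006	1.364e-17	26420
rs9000008	G	A	0.529	0.043598	0.006	3.693e-13	26420
rs9000009	C	T	0.58	0.049039	0.006	3.005e-16	26420
rs9000010	A	G	0.813	0.043474	0.006	4.302e-13	26420
rs9000011	T	C	0.523	0.042722	0.006	1.076e-12	26420
rs9000012	G	A	0.614	0.04984	0.006	9.846e-17	26420
rs9000013	C	T	0.713	0.048781	0.006	4.286e-16	26420
rs9000014	A	G	0.634	0.048411	0.006	7.119e-16	26420
rs9000015	T	C	0.785	0.043927	0.006	2.458e-13	26420
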