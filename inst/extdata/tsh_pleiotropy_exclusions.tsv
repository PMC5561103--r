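SNP	reason	annotation
rs13015993	pleiotropy	IGFBP5_CAD_association
rs7568039	pleiotropy	IGFBP2_CAD_association
rs657152	pleiotropy	ABO_IHD_association
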