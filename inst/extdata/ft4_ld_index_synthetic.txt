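rs7860634
rs11726248
rs11103377
rs7694879
rs113107469
rs7045138
rs9100001
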