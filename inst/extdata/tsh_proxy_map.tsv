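target	proxy
rs2928167	rs12523579
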