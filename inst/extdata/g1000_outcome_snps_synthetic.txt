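rs12410532
rs28435578
rs2046045
rs6923866
rs2396084
rs3008034
rs116552240
rs17767742
rs10799824
rs10032216
rs6885099
rs11755845
rs9472138
rs753760
rs657152
rs3813582
rs13015993
rs7568039
rs9000002
rs9000003
rs9000004
rs9000005
rs9000006
rs9000007
rs9000008
rs9000009
rs9000010
rs9000011
rs9000012
rs9000013
rs9000014
rs9000015
rs12523579
rs7860634
rs11726248
rs11103377
rs7694879
rs113107469
rs9100001
rs4297160
rs653178
rs9200001
rs9200002
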