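"SEQN","INDFMPIR"
1,0.8
2,1.5
3,2.2
4,3.1
5,0.4
6,NA
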