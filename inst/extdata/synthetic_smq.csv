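"SEQN","SMD460"
1,0
2,1
3,0
4,2
5,1
6,0
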