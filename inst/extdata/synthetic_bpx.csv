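"SEQN","BPXOSY1","BPXOSY2","BPXOSY3","BPXODI1","BPXODI2","BPXODI3"
1,98,102,NA,60,62,NA
2,104,106,105,64,66,65
3,99,97,98,58,56,57
4,101,99,100,61,59,60
5,NA,NA,NA,NA,NA,NA
6,95,97,96,55,57,56
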