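"SEQN","RIDAGEYR","RIAGENDR","RIDRETH3","WTMECPRP","SDMVSTRA","SDMVPSU"
1,9,1,1,12000,171,1
2,10,2,3,9000,171,2
3,5,1,3,8000,172,1
4,14,2,4,7000,172,2
5,8,2,6,15000,173,1
6,11,1,3,11000,173,2
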