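item,r1,r2,r3,r4,r5,r6,r7
INT,4,4,4,5,4,4,4
PU1,5,5,5,5,4,5,5
PU2,5,5,5,5,5,5,4
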