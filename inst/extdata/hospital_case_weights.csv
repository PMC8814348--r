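criterion,dimension,weight
C11,D1,0.292
C12,D1,0.223
C13,D1,0.165
C14,D1,0.320
C21,D2,0.247
C22,D2,0.259
C23,D2,0.341
C24,D2,0.153
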