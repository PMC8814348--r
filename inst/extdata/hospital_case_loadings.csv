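item,D1,D2
C11,0.947,
C12,0.920,
C13,0.889,
C14,0.880,
C21,,0.954
C22,,0.926
C23,,0.904
C24,,0.801
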