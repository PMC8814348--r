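alternative,C11,C12,C13,C14,C21,C22,C23,C24
SYUH,0.551,0.407,0.516,0.420,0.623,0.465,0.542,0.710
GZMH,0.689,0.598,0.377,0.596,0.430,0.734,0.425,0.522
ZCWH,0.470,0.690,0.769,0.685,0.653,0.494,0.725,0.473
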