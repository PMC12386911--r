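plot,original,preprocessed
A,443,353
B,398,263
C,572,449
D,338,265
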