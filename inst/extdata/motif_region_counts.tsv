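region	n_occurrences
utr5	115
cds	470
utr3	1341
other	175
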