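group	n_enriched	n_sheaths
sv40	10	35
mbpa	18	38
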