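sequence_type	n_input_sequences	n_occurrences	n_unique_with_hit
cdna_mouse_transcriptome	56289	36662	16144
cdna_myelin_transcriptome	1771	2101	751
utr5_myelin	1195	115	59
cds_myelin	1411	470	751
utr3_myelin	1404	1341	480
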