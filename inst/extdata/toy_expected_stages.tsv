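stage	proteins_in	proteins_out	removed
min_peptides	8	6	P4,P8
control_enrichment	6	4	P5,P7
replicate_presence	4	3	P6
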