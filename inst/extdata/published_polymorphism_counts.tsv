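type	count
SNP	19
INDEL	6
TE_INSERTION	147
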