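element	ltr1	ltr2	ltr3	ltr4	minor
Gret-1	25	18	5	3	49
Copia-10	19	7	7	3	64
Gypsy-19	10	NA	NA	NA	90
Cauliv-1	7	NA	NA	NA	93
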