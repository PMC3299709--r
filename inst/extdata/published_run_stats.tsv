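clone	size_mb	n_reads	mean_length	mean_quality	n_duplicated	pct_duplicated
PN386	330	941498	351	31	12239	1.30
PN583	378	1052396	361	28	2420	0.23
PN777	344	988669	354	31	2642	0.26
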