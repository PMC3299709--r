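row	category	PN386	PN583	PN777	mean3	PN115
aligned	step1	48.1	42.5	40.2	43.6	57.7
aligned	step2	0.9	1.1	1.0	1.0	1.3
aligned	step3	12.5	21.7	16.7	16.9	8.0
aligned	total	61.5	65.3	57.9	61.5	67.0
unaligned	repeat_elements	12.5	13.4	13.9	13.2	12.7
unaligned	paralogs	12.0	10.1	13.0	11.7	20.3
unaligned	cytoplasmic	4.2	3.6	3.7	3.8	NA
unaligned	unknown	8.1	6.8	10.4	8.4	NA
unaligned	contamination	0.01	0.01	0.01	0.01	NA
unaligned	low_quality	1.7	0.8	1.4	1.3	NA
unaligned	total	38.5	34.8	42.1	38.4	33.0
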