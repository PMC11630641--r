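species	target	qflow_copies	proteomics_copies	printed_fold
mouse	CD11b	70054	408674	5.8
mouse	Ly-6G	171919	190665	1.1
mouse	CXCR2	16530	24317	1.4
human	CD11b	284704	829809	2.9
human	CXCR2	24349	12895	1.8
human	CD82	20200	18199	1.1
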