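stage	description	n_probesets	n_genes
0	input probesets (core exon/gene signal estimates)	221336	16661
1	remove first/last probeset of each gene	188374	15753
2	remove probesets with sequence length >= 500 nt	185028	15654
3	remove cross-hybridizing probesets	159552	15238
4	keep genes expressed on both day 0 and day 7	102661	8601
5	keep probesets detected on day 0 or day 7	94780	8541
6	keep |si_d7| >= 1.35	1636	948
7	remove probesets whose detectable neighbors all changed	1107	805
8	keep probesets predicted alternative	309	278
9	keep probesets whose day-7 effect exceeds day 10	262	236
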