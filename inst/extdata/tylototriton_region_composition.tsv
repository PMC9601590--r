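#species	region	size	pct_A	pct_T	pct_C	pct_G	at_content	at_skew	gc_skew
Tylototriton broadoridgus	D-loop	716	28.6	34.9	21.2	15.2	63.5	-0.10	-0.17
Tylototriton broadoridgus	12S-rRNA	928	37.9	19.9	23.9	18.2	57.8	0.31	-0.14
Tylototriton broadoridgus	16S-rRNA	1563	40.2	23.3	20.3	16.3	63.5	0.27	-0.11
Tylototriton broadoridgus	tRNAs	1537	32.3	30.1	17.7	19.8	62.4	0.04	0.06
Tylototriton broadoridgus	PCGs-1st	3795	30	25.4	25.1	19.4	55.4	0.08	-0.13
Tylototriton broadoridgus	PCGs-2nd	3794	25.1	33.6	27.9	13.5	58.7	-0.14	-0.35
Tylototriton broadoridgus	PCGs-3rd	3794	37.8	23	28.1	11.1	60.8	0.24	-0.43
Tylototriton broadoridgus	PCGs	11383	31	27.3	27	14.7	58.3	0.06	-0.29
Tylototriton broadoridgus	Genome	16265	33.6	25.7	26.3	14.5	59.3	0.13	-0.29
Tylototriton gaowangjienensis	D-loop	715	29.0	34.5	21.0	15.5	63.5	-0.09	-0.15
Tylototriton gaowangjienensis	12S-rRNA	927	38.1	20.1	23.7	18.1	58.2	0.31	-0.13
Tylototriton gaowangjienensis	16S-rRNA	1560	40.1	23.4	20.1	16.4	63.5	0.26	-0.10
Tylototriton gaowangjienensis	tRNAs	1537	32.1	30.0	17.9	20.0	62.1	0.03	0.05
Tylototriton gaowangjienensis	PCGs-1st	3795	30.3	25.1	25.2	19.3	55.4	0.09	-0.13
Tylototriton gaowangjienensis	PCGs-2nd	3794	25	33.4	28	13.5	58.4	-0.14	-0.35
Tylototriton gaowangjienensis	PCGs-3rd	3794	37	23	28	11.4	60.0	0.23	-0.42
Tylototriton gaowangjienensis	PCGs	11383	31	27.2	27.1	14.8	58.2	0.07	-0.29
Tylototriton gaowangjienensis	Genome	16259	33.6	25.6	26.3	14.6	59.2	0.14	-0.29
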