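center	n_screened	msms_positive	msms_recalled	msms_confirmed	msms_false_negative	ngs_positive	ngs_recalled	ngs_confirmed	ngs_false_negative
SH	4888	47	41	1	0	1	1	1	0
GZ	4813	50	47	4	1	5	5	4	1
JN	4797	149	138	6	0	6	6	4	2
SJZ	4899	67	65	2	0	1	1	1	1
CQ	2988	30	22	2	0	3	3	1	1
YN	3006	43	40	2	1	3	3	3	0
NMG	3233	113	36	2	0	3	3	2	0
HN	977	8	8	2	0	2	2	1	1
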