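center_id	marker	threshold	direction	unit
REF	C0	10	low	umol/L
REF	C3	4.5	high	umol/L
REF	C3/C2	0.2	high	ratio
REF	C4	0.46	high	umol/L
REF	C4/C3	0.4	high	ratio
REF	C5	0.35	high	umol/L
REF	C6	0.12	high	umol/L
REF	C8	0.16	high	umol/L
REF	C8/C10	1.4	high	ratio
REF	C12	0.3	high	umol/L
REF	C14	0.4	high	umol/L
REF	C16	4.27	high	umol/L
REF	C18	1.8	high	umol/L
REF	C18:1	3	high	umol/L
REF	Met	9	low	umol/L
REF	Phe	120	high	umol/L
REF	Phe/Tyr	1.5	high	ratio
REF	Cit	30	high	umol/L
REF	Leu	270	high	umol/L
REF	Val	269	high	umol/L
REF	Pro	400	high	umol/L
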