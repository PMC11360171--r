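endpoint	model	n_active	n_inactive	se	sp	ba	mcc
ER	MCF7	100	191	0.610	0.817	0.713	0.431
ER	A549	100	191	0.540	0.791	0.665	0.336
ER	consensus	100	191	0.570	0.880	0.725	0.478
AR	MCF7	45	155	0.711	0.710	0.710	0.361
AR	A549	45	155	0.867	0.742	0.804	0.520
AR	consensus	45	155	0.622	0.903	0.763	0.534
TR	MCF7	56	94	0.786	0.862	0.824	0.645
TR	A549	56	94	0.732	0.851	0.792	0.585
TR	consensus	56	94	0.786	0.893	0.840	0.684
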