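chromosome	genotype	interval	cM
X	control	sc-cv	13.6
X	control	cv-v	20.8
X	control	v-f	19.5
X	control	f-y+	7.3
X	mau	sc-cv	20.3
X	mau	cv-v	23.8
X	mau	v-f	25.0
X	mau	f-y+	15.0
3	control	ru-h	24.8
3	control	h-th	19.1
3	control	th-st	0.8
3	control	st-cu	7.4
3	mau	ru-h	25.6
3	mau	h-th	23.0
3	mau	th-st	0.8
3	mau	st-cu	20.1
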