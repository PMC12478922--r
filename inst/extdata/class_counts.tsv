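chromosome	genotype	class_index	count
X	control	0	1233
X	control	1	1182
X	control	2	207
X	control	3	4
X	mau	0	565
X	mau	1	689
X	mau	2	271
X	mau	3	24
3	control	0	1001
3	control	1	759
3	control	2	96
3	control	3	6
3	mau	0	662
3	mau	1	753
3	mau	2	169
3	mau	3	5
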