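elem1	elem2	single_max	double_max
C	C	1.58	1.40
C	H	1.13	NA
C	N	1.53	1.33
C	O	1.48	1.30
C	P	1.89	1.75
C	S	1.87	1.67
H	H	0.68	NA
H	N	1.08	NA
H	O	1.03	NA
H	P	1.44	NA
H	S	1.42	NA
N	N	1.48	1.26
N	O	1.43	1.23
N	P	1.84	1.68
N	S	1.82	1.60
O	O	1.38	1.20
O	P	1.79	1.65
O	S	1.77	1.57
P	P	2.20	2.10
P	S	2.18	2.02
S	S	2.16	1.94
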