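position	residue	A	C	G	T
-1	A	0.7	0.1	0.1	0.1
-1	C	0.1	0.1	0.1	0.7
-1	D	0.1	0.7	0.1	0.1
-1	E	0.1	0.7	0.1	0.1
-1	F	0.1	0.1	0.1	0.7
-1	G	0.7	0.1	0.1	0.1
-1	H	0.1	0.1	0.7	0.1
-1	I	0.1	0.1	0.1	0.7
-1	K	0.1	0.1	0.7	0.1
-1	L	0.1	0.1	0.1	0.7
-1	M	0.7	0.1	0.1	0.1
-1	N	0.7	0.1	0.1	0.1
-1	P	0.1	0.7	0.1	0.1
-1	Q	0.7	0.1	0.1	0.1
-1	R	0.1	0.1	0.7	0.1
-1	S	0.1	0.7	0.1	0.1
-1	T	0.1	0.1	0.1	0.7
-1	V	0.7	0.1	0.1	0.1
-1	W	0.1	0.1	0.1	0.7
-1	Y	0.1	0.1	0.1	0.7
2	A	0.7	0.1	0.1	0.1
2	C	0.1	0.1	0.1	0.7
2	D	0.1	0.7	0.1	0.1
2	E	0.1	0.7	0.1	0.1
2	F	0.1	0.1	0.1	0.7
2	G	0.7	0.1	0.1	0.1
2	H	0.1	0.1	0.7	0.1
2	I	0.1	0.1	0.1	0.7
2	K	0.1	0.1	0.7	0.1
2	L	0.1	0.1	0.1	0.7
2	M	0.7	0.1	0.1	0.1
2	N	0.7	0.1	0.1	0.1
2	P	0.1	0.7	0.1	0.1
2	Q	0.7	0.1	0.1	0.1
2	R	0.1	0.1	0.7	0.1
2	S	0.1	0.7	0.1	0.1
2	T	0.1	0.1	0.1	0.7
2	V	0.7	0.1	0.1	0.1
2	W	0.1	0.1	0.1	0.7
2	Y	0.1	0.1	0.1	0.7
3	A	0.7	0.1	0.1	0.1
3	C	0.1	0.1	0.1	0.7
3	D	0.1	0.7	0.1	0.1
3	E	0.1	0.7	0.1	0.1
3	F	0.1	0.1	0.1	0.7
3	G	0.7	0.1	0.1	0.1
3	H	0.1	0.1	0.7	0.1
3	I	0.1	0.1	0.1	0.7
3	K	0.1	0.1	0.7	0.1
3	L	0.1	0.1	0.1	0.7
3	M	0.7	0.1	0.1	0.1
3	N	0.7	0.1	0.1	0.1
3	P	0.1	0.7	0.1	0.1
3	Q	0.7	0.1	0.1	0.1
3	R	0.1	0.1	0.7	0.1
3	S	0.1	0.7	0.1	0.1
3	T	0.1	0.1	0.1	0.7
3	V	0.7	0.1	0.1	0.1
3	W	0.1	0.1	0.1	0.7
3	Y	0.1	0.1	0.1	0.7
6	A	0.7	0.1	0.1	0.1
6	C	0.1	0.1	0.1	0.7
6	D	0.1	0.7	0.1	0.1
6	E	0.1	0.7	0.1	0.1
6	F	0.1	0.1	0.1	0.7
6	G	0.7	0.1	0.1	0.1
6	H	0.1	0.1	0.7	0.1
6	I	0.1	0.1	0.1	0.7
6	K	0.1	0.1	0.7	0.1
6	L	0.1	0.1	0.1	0.7
6	M	0.7	0.1	0.1	0.1
6	N	0.7	0.1	0.1	0.1
6	P	0.1	0.7	0.1	0.1
6	Q	0.7	0.1	0.1	0.1
6	R	0.1	0.1	0.7	0.1
6	S	0.1	0.7	0.1	0.1
6	T	0.1	0.1	0.1	0.7
6	V	0.7	0.1	0.1	0.1
6	W	0.1	0.1	0.1	0.7
6	Y	0.1	0.1	0.1	0.7
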