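variant	position	wt_aa	mut_aa	condition	replicate	timepoint	count
L1100A	1100	L	A	DMSO	1	0	36
L1100A	1100	L	A	DMSO	1	1	38
L1100A	1100	L	A	DMSO	1	2	45
L1100A	1100	L	A	DMSO	1	3	37
L1100A	1100	L	A	DMSO	2	0	45
L1100A	1100	L	A	DMSO	2	1	51
L1100A	1100	L	A	DMSO	2	2	57
L1100A	1100	L	A	DMSO	2	3	44
L1100A	1100	L	A	DMSO	3	0	42
L1100A	1100	L	A	DMSO	3	1	36
L1100A	1100	L	A	DMSO	3	2	37
L1100A	1100	L	A	DMSO	3	3	32
L1100K	1100	L	K	DMSO	1	0	53
L1100K	1100	L	K	DMSO	1	1	30
L1100K	1100	L	K	DMSO	1	2	45
L1100K	1100	L	K	DMSO	1	3	29
L1100K	1100	L	K	DMSO	2	0	51
L1100K	1100	L	K	DMSO	2	1	28
L1100K	1100	L	K	DMSO	2	2	42
L1100K	1100	L	K	DMSO	2	3	35
L1100K	1100	L	K	DMSO	3	0	41
L1100K	1100	L	K	DMSO	3	1	30
L1100K	1100	L	K	DMSO	3	2	30
L1100K	1100	L	K	DMSO	3	3	41
L1100L	1100	L	L	DMSO	1	0	47
L1100L	1100	L	L	DMSO	1	1	42
L1100L	1100	L	L	DMSO	1	2	29
L1100L	1100	L	L	DMSO	1	3	37
L1100L	1100	L	L	DMSO	2	0	46
L1100L	1100	L	L	DMSO	2	1	39
L1100L	1100	L	L	DMSO	2	2	50
L1100L	1100	L	L	DMSO	2	3	33
L1100L	1100	L	L	DMSO	3	0	39
L1100L	1100	L	L	DMSO	3	1	39
L1100L	1100	L	L	DMSO	3	2	34
L1100L	1100	L	L	DMSO	3	3	55
P1101*	1101	P	*	DMSO	1	0	43
P1101*	1101	P	*	DMSO	1	1	40
P1101*	1101	P	*	DMSO	1	2	37
P1101*	1101	P	*	DMSO	1	3	0
P1101*	1101	P	*	DMSO	2	0	34
P1101*	1101	P	*	DMSO	2	1	38
P1101*	1101	P	*	DMSO	2	2	49
P1101*	1101	P	*	DMSO	2	3	0
P1101*	1101	P	*	DMSO	3	0	44
P1101*	1101	P	*	DMSO	3	1	40
P1101*	1101	P	*	DMSO	3	2	39
P1101*	1101	P	*	DMSO	3	3	0
P1101R	1101	P	R	DMSO	1	0	30
P1101R	1101	P	R	DMSO	1	1	50
P1101R	1101	P	R	DMSO	1	2	46
P1101R	1101	P	R	DMSO	1	3	47
P1101R	1101	P	R	DMSO	2	0	37
P1101R	1101	P	R	DMSO	2	1	41
P1101R	1101	P	R	DMSO	2	2	44
P1101R	1101	P	R	DMSO	2	3	48
P1101R	1101	P	R	DMSO	3	0	39
P1101R	1101	P	R	DMSO	3	1	39
P1101R	1101	P	R	DMSO	3	2	40
P1101R	1101	P	R	DMSO	3	3	35
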