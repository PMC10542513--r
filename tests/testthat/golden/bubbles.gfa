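H	VN:Z:1.0
S	1	GTAGACATTACGGTCATATTTCGT
S	2	ATTCCTAAAAC
S	3	CTCTTCCCTGCCGGCCAAG
S	4	TCT
S	5	GAGCGAT
S	6	ATTCATATTGAT
S	7	TCTTAACAACGCTCAATGG
S	8	CAGCAAGGAAGTTTTTTAGGGG
S	9	GAACCAAGGATAGAGTACCAA
S	10	GCGGCCATGATGGCCCCGAGTTGATT
S	11	GAGGTCGTAGCATTCTGCT
S	12	CTTACACCGACCCATCTCATCCGG
S	13	AACGGCGGGTAACACATTTTCTCTTCAAGA
S	14	CTATGGCGCTCGCGATCATTGGTAAGCTGA
S	15	AATTTG
S	16	CC
S	17	CCTATGCACTCTTACTTTCATACC
S	18	G
S	19	GGGAAGTGTAATAAAAACGG
S	20	AGACGGAACCCCATGAGCAAACATTTGGCCA
S	21	TATTGGGGAGC
S	22	ACT
S	23	GGTCCAAGTACTGGATGCGATTCTGGG
S	24	TTGAGAAAAAATC
S	25	ACCAAAAAAGTGAAGA
S	26	ACGGCGCCCTTCGATC
S	27	AGCTA
S	28	CCAGAATAGCGACGCGCCTAGCCGAGCGT
S	29	CC
S	30	CACACCGGTTCCAGGTCGTTTGTCTCGGGTTA
S	31	A
S	32	T
S	33	G
S	34	G
S	35	G
S	36	G
S	37	A
S	38	A
S	39	T
S	40	G
S	41	A
S	42	T
S	43	G
S	44	A
S	45	C
S	46	T
S	47	A
S	48	C
S	49	A
S	50	A
S	51	G
S	52	T
S	53	T
S	54	G
S	55	A
S	56	G
S	57	T
S	58	C
S	59	C
S	60	C
S	61	T
S	62	C
S	63	C
S	64	C
S	65	A
S	66	A
S	67	A
S	68	T
L	1	+	2	+	0M
L	2	+	3	+	0M
L	3	+	31	+	0M
L	3	+	32	+	0M
L	4	+	33	+	0M
L	4	+	34	+	0M
L	5	+	35	+	0M
L	5	+	36	+	0M
L	6	+	7	+	0M
L	7	+	37	+	0M
L	7	+	38	+	0M
L	8	+	9	+	0M
L	9	+	10	+	0M
L	10	+	39	+	0M
L	10	+	40	+	0M
L	11	+	41	+	0M
L	11	+	42	+	0M
L	12	+	43	+	0M
L	12	+	44	+	0M
L	13	+	14	+	0M
L	14	+	45	+	0M
L	14	+	46	+	0M
L	15	+	47	+	0M
L	15	+	48	+	0M
L	16	+	49	+	0M
L	16	+	50	+	0M
L	17	+	18	+	0M
L	18	+	19	+	0M
L	19	+	51	+	0M
L	19	+	52	+	0M
L	20	+	21	+	0M
L	21	+	53	+	0M
L	21	+	54	+	0M
L	22	+	55	+	0M
L	22	+	56	+	0M
L	23	+	57	+	0M
L	23	+	58	+	0M
L	24	+	59	+	0M
L	24	+	60	+	0M
L	25	+	61	+	0M
L	25	+	62	+	0M
L	26	+	63	+	0M
L	26	+	64	+	0M
L	27	+	28	+	0M
L	28	+	65	+	0M
L	28	+	66	+	0M
L	29	+	67	+	0M
L	29	+	68	+	0M
L	31	+	4	+	0M
L	32	+	4	+	0M
L	33	+	5	+	0M
L	34	+	5	+	0M
L	35	+	6	+	0M
L	36	+	6	+	0M
L	37	+	8	+	0M
L	38	+	8	+	0M
L	39	+	11	+	0M
L	40	+	11	+	0M
L	41	+	12	+	0M
L	42	+	12	+	0M
L	43	+	13	+	0M
L	44	+	13	+	0M
L	45	+	15	+	0M
L	46	+	15	+	0M
L	47	+	16	+	0M
L	48	+	16	+	0M
L	49	+	17	+	0M
L	50	+	17	+	0M
L	51	+	20	+	0M
L	52	+	20	+	0M
L	53	+	22	+	0M
L	54	+	22	+	0M
L	55	+	23	+	0M
L	56	+	23	+	0M
L	57	+	24	+	0M
L	58	+	24	+	0M
L	59	+	25	+	0M
L	60	+	25	+	0M
L	61	+	26	+	0M
L	62	+	26	+	0M
L	63	+	27	+	0M
L	64	+	27	+	0M
L	65	+	29	+	0M
L	66	+	29	+	0M
L	67	+	30	+	0M
L	68	+	30	+	0M
P	p1	1+,2+,3+,31+,4+,33+,5+,35+,6+,7+,38+,8+,9+,10+,40+,11+,41+,12+,43+,13+,14+,46+,15+,48+,16+,50+,17+,18+,19+,51+,20+,21+,54+,22+,55+,23+,58+,24+,59+,25+,62+,26+,63+,27+,28+,65+,29+,68+,30+	*
P	p2	1+,2+,3+,32+,4+,34+,5+,35+,6+,7+,37+,8+,9+,10+,39+,11+,42+,12+,43+,13+,14+,45+,15+,48+,16+,50+,17+,18+,19+,52+,20+,21+,54+,22+,55+,23+,57+,24+,60+,25+,61+,26+,64+,27+,28+,65+,29+,67+,30+	*
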