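idx	X	Y
0	59.806645495053708	-5.7290960898854228
1	143.43769594927915	-8.2684968410363595
2	143.4394870869009	-8.2685284938051975
3	154.38672882822658	-10.201059878691101
4	154.38617242859692	-10.201127221945372
5	173.29882866844795	-6.3537397950005046
6	174.20757230382412	-5.9022642868903636
7	177.32039151525476	-5.8407784402190117
8	178.28068717247189	-6.2091595720084705
9	184.59784892765862	-2.560850754850859
10	185.44268359968729	-2.0239173649828563
11	196.97284390954485	2.0746256558390339
12	196.97210780973384	2.0744275357268558
13	216.25029435971459	5.1767778317390274
14	216.78884731490368	6.0222287139806054
15	238.69039512265093	12.841710689460699
16	238.6896057897159	12.841666032102884
17	260.274558497344	9.189012856570475
18	260.27374046716648	9.1891439735860132
19	287.00579739629023	5.0597486307197705
20	287.52464050325761	4.1804435672816584
21	305.95668678253821	-4.2629047955342623
22	306.34919642547572	-5.1929043815566409
23	330.94892947954349	-7.6817114371118471
24	331.77054812938309	-8.2537229462896438
25	362.25995461437947	-10.489588985894512
26	362.2595453422511	-10.489622893387489
27	392.63964859105192	-2.6227369642546399
28	393.46130663672034	-3.2087985027655548
29	399.23447280268709	-5.3186482480773156
30	400.07095252634281	-5.874617659965085
31	402.02004624241852	-6.4584592909188379
32	403.0093685173054	-6.6301093225006689
33	427.39886317236648	-3.6040863527153943
34	427.39821227729789	-3.6042638150642556
35	428.26517948005522	-3.1012471075172341
36	428.26476938698835	-3.1014027279211627
37	448.25995790233668	2.0226212345695544
38	448.67219710176528	2.9456182532309003
39	480.38949287901784	1.6582921957945562
40	480.38906158308106	1.6584170110480809
41	491.41594671251755	-1.3501373498431068
42	492.3333081958927	-0.93432720117886259
43	495.05554887337667	0.4524990603318243
44	495.86814737629783	1.0412834595609577
45	523.30496900351852	3.8849581602975514
46	524.06445416803331	3.2255221401437266
47	537.35675655082002	1.6580375153046329
48	538.22399140646269	2.1633778760131523
49	554.23005989985711	6.2751125220652915
50	555.09834445692616	5.7644561223652291
51	571.13475823587203	1.6338270947515987
52	572.08397174103243	1.9866641707010662
53	576.93121798800871	3.380855261784447
54	576.93084519495812	3.38075296984089
55	606.0048032446997	7.397720959930524
56	607.00366972756615	7.3456142712512014
57	608.97110131827355	6.9182569927984501
58	609.82774816420704	6.3952459968818234
59	543.68253279702685	2.0500990035953688
60	173.29652246243396	-6.3547278350317127
61	174.21226147955539	-5.9013052023588388
62	173.29529581892069	-6.3552750892599246
63	174.20907533190328	-5.9006766837185918
64	177.31620036626484	-5.8395104371450843
65	178.2954073053823	-6.2154540721586367
66	177.3173788233089	-5.8405447162779254
67	178.28458093928646	-6.2093312473209021
68	184.59756730686064	-2.5610163474918486
69	185.44312465799425	-2.0236860156680012
70	510	-0.20409732081957599
71	511	-0.22561418551735526
72	216.2497954004233	5.1763792486526405
73	216.78919870807658	6.0226251439794964
74	216.2491486472648	5.1759325951855217
75	216.78957481493254	6.0228331646750624
76	287.0014502896405	5.0664286823071274
77	287.52542227423015	4.1799298167058518
78	287.00397603553495	5.0625510491568448
79	287.53141012301313	4.1692294028325625
80	305.95544601274406	-4.26093136099073
81	306.3501323174998	-5.1943919578310664
82	305.95551126559644	-4.2619700069661146
83	306.35037129732422	-5.1938396783655749
84	330.94842713400988	-7.6815206957642292
85	331.77104041234458	-8.2538807491710493
86	518	2.3872326463773925
87	519	-0.47343201219646341
88	392.63926777846189	-2.6230034242938514
89	393.46260587103347	-3.209773602210535
90	392.63724828560237	-2.6211785828276475
91	393.46170766588079	-3.2086667346621902
92	521	0.55703386629795926
93	522	0.90073058491217139
94	399.23268697002311	-5.3177934283585051
95	400.07363870160236	-5.8757178657993983
96	523	-0.34658381369871805
97	524	-0.54018925000441931
98	402.01875124511594	-6.4581281759262303
99	403.01004443563079	-6.63014484775419
100	448.25972398264554	2.0221591484241999
101	448.67252375903803	2.9462919394155294
102	448.25961110329627	2.0221912369324841
103	448.67274316058717	2.9459803902646748
104	527	-0.057845642085054341
105	528	0.89381141410259368
106	491.41459569919738	-1.3504087137339775
107	492.33465947734766	-0.93375556384191361
108	495.05422235609694	0.45162598832064976
109	495.86917592722619	1.0419309922593869
110	530	-0.95290495974216249
111	531	1.6223793930093771
112	523.30142417929619	3.887703409520467
113	524.06615330504053	3.2245900153648432
114	523.3047951906085	3.8851045237475179
115	524.06645335751045	3.2238664719939396
116	537.35596509120774	1.6578031617228088
117	538.22446365924134	2.1636021068475735
118	537.35579722962245	1.6578112201496438
119	538.22466587221572	2.1635627263328292
120	554.2284707645872	6.2760092700581049
121	555.10231730053977	5.7621569327034043
122	554.22889294661479	6.2756367627891363
123	555.09880757401527	5.7644173162052841
124	571.1314804239878	1.6328271674990367
125	572.08596442639123	1.9872758737389424
126	571.1335157888326	1.6333054181449109
127	572.08645431825073	1.987310063382451
128	606.004864403375	7.3976668111422912
129	607.00388014222517	7.3456267988646946
130	540	1.3485490550277814
131	541	-1.9785283396939293
132	608.96949428954872	6.9190897878155564
133	609.82899993268313	6.3946587774559154
134	608.96902359096623	6.9194682370475498
135	609.82845249583136	6.3950097014606495
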