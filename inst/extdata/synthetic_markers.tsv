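CHROM	POS	SUPERIOR_COUNT	TOTAL_COUNT
chrS	224	135	200
chrS	1024	145	200
chrS	1385	143	200
chrS	1761	136	200
chrS	1989	140	200
chrS	2435	136	200
chrS	2589	141	200
chrS	2856	146	200
chrS	5772	160	200
chrS	7802	153	200
chrS	7847	138	200
chrS	7963	164	200
chrS	8243	162	200
chrS	9369	154	200
chrS	10965	156	200
chrS	11010	156	200
chrS	11024	165	200
chrS	12578	156	200
chrS	12749	160	200
chrS	13005	140	200
chrS	14444	145	200
chrS	16080	149	200
chrS	17086	155	200
chrS	17090	160	200
chrS	18233	160	200
chrS	18748	164	200
chrS	19507	160	200
chrS	19872	157	200
chrS	20179	158	200
chrS	22955	163	200
chrS	25436	162	200
chrS	25687	138	200
chrS	27132	162	200
chrS	27958	152	200
chrS	28654	169	200
chrS	29018	162	200
chrS	29307	162	200
chrS	29372	152	200
chrS	31432	160	200
chrS	31496	163	200
chrS	31649	159	200
chrS	32080	164	200
chrS	32549	151	200
chrS	33332	165	200
chrS	33803	159	200
chrS	34760	155	200
chrS	36504	167	200
chrS	38169	141	200
chrS	40610	155	200
chrS	40762	151	200
chrS	42426	163	200
chrS	44536	168	200
chrS	45756	167	200
chrS	45969	170	200
chrS	46434	169	200
chrS	46754	173	200
chrS	47110	173	200
chrS	47279	168	200
chrS	48714	162	200
chrS	52044	171	200
chrS	52333	173	200
chrS	52626	165	200
chrS	53232	169	200
chrS	53367	170	200
chrS	53401	172	200
chrS	53451	178	200
chrS	54036	179	200
chrS	56625	180	200
chrS	59202	167	200
chrS	59581	176	200
chrS	60841	168	200
chrS	61005	157	200
chrS	65173	172	200
chrS	65229	180	200
chrS	66112	171	200
chrS	66411	179	200
chrS	66471	181	200
chrS	66691	185	200
chrS	67889	181	200
chrS	68137	181	200
chrS	69605	185	200
chrS	69700	187	200
chrS	69750	187	200
chrS	70841	194	200
chrS	71591	195	200
chrS	72876	191	200
chrS	74817	191	200
chrS	74867	190	200
chrS	75044	195	200
chrS	77320	193	200
chrS	77425	190	200
chrS	77547	183	200
chrS	83836	192	200
chrS	84361	192	200
chrS	84561	196	200
chrS	84693	194	200
chrS	84898	191	200
chrS	86565	182	200
chrS	90378	174	200
chrS	92184	187	200
chrS	92263	176	200
chrS	94635	180	200
chrS	95093	175	200
chrS	95773	178	200
chrS	95947	177	200
chrS	98749	165	200
chrS	102928	165	200
chrS	103504	180	200
chrS	104894	174	200
chrS	107285	172	200
chrS	107441	170	200
chrS	108167	156	200
chrS	109486	161	200
chrS	110164	159	200
chrS	112451	153	200
chrS	114105	156	200
chrS	114325	159	200
chrS	115830	147	200
chrS	118426	138	200
chrS	119457	155	200
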