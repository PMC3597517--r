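patient_code	chrom	start_hg19	end_hg19	size_kb	mh_len	scar	repeat_prox	motifs_prox	nonb_prox	repeat_dist	motifs_dist	nonb_dist	identity_pct	mechanism	deletion_class
A	3	138949150	138956510	7	0	NA	NA	8	0	NA	6	0	NA	NHEJ	regulatory
B	3	138912808	139012600	100	5	NA	L1PA4	6	0	MIRb	10	0	NA	Replicative/MMEJ	regulatory
C	3	138867472	139048942	181	1	NA	L1ME3F	3	0	MIRc	8	0	NA	Replicative/NHEJ	regulatory
D	3	138479902	138662725	183	2	NA	NA	4	0	NA	7	0	NA	Replicative/NHEJ	regulatory
E	3	138805920	139012140	206	1	TC>AA	L1M7	7	0	NA	11	0	NA	Replicative/NHEJ	regulatory
F	3	138938973	139294473	356	1	NA	L1Med	30	0	NA	3	0	NA	Replicative/NHEJ	regulatory
G	3	138745991	140393036	1647	33	NA	L1PA5	9	0	L1PA4	8	0	93	NAHR/Replicative/MMEJ	regulatory
H	3	138741281	141762242	3021	12	NA	AluSz	8	1	AluSz	17	0	83	NAHR/Replicative/MMEJ	regulatory
1	3	138664845	138666255	1	5	NA	NA	6	3	NA	15	1	NA	Replicative/MMEJ	foxl2_encompassing
2	3	138658319	138666527	8	4	NA	NA	5	1	NA	5	1	NA	Replicative/NHEJ	foxl2_encompassing
3	3	138649686	138736058	86	1	C>A	NA	12	1	NA	5	0	NA	Replicative/NHEJ	foxl2_encompassing
4	3	138661542	138786728	125	1	NA	NA	0	0	L1PA2	8	0	NA	Replicative/NHEJ	foxl2_encompassing
5	3	138475828	138857284	381	1	NA	L1MB4	7	0	NA	40	1	NA	Replicative/NHEJ	foxl2_encompassing
6	3	138019964	139735421	1715	0	del(T)	Tigger15a	2	0	AluSc	6	1	NA	NHEJ	foxl2_encompassing
7	3	137894385	139735424	1841	15	NA	AluSx3	7	1	AluSc	6	2	85	NAHR/Replicative/MMEJ	foxl2_encompassing
8	3	136887871	138746237	1858	66	NA	L1PA3	4	0	L1PA5	4	0	93	NAHR/Replicative/MMEJ	foxl2_encompassing
9	3	138532388	140753510	2221	15	NA	AluY	8	0	AluY	14	1	85	NAHR/Replicative/MMEJ	foxl2_encompassing
10	3	136604806	139000361	2396	2	NA	NA	7	0	NA	11	0	NA	Replicative/NHEJ	foxl2_encompassing
11	3	136007507	138671922	2664	34	NA	AluJo	7	0	AluSz	10	1	77	NAHR/Replicative/MMEJ	foxl2_encompassing
12	3	138134298	141034621	2900	1	NA	AluJr	16	0	Charlie1a	7	0	NA	Replicative/NHEJ	foxl2_encompassing
13	3	138602856	142458004	3855	26	NA	AluSp	9	0	AluSp	12	0	89	NAHR/Replicative/MMEJ	foxl2_encompassing
14	3	137934887	142100431	4166	25	NA	AluSx3	36	1	AluSz6	36	1	74	NAHR/Replicative/MMEJ	foxl2_encompassing
15	3	135099979	139713853	4614	1	NA	LTR33A	3	0	NA	7	0	NA	Replicative/NHEJ	foxl2_encompassing
16	3	136887730	142397685	5510	5	NA	L1PA3	9	0	L1PA3	6	0	96	NAHR/Replicative/MMEJ	foxl2_encompassing
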