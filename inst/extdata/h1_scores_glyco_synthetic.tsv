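seq_id	position	residue	predictor	score	threshold
Q02539	1	S	glyco	0.2	0.5
Q02539	11	T	glyco	0.2	0.5
Q02539	33	S	glyco	0.7	0.5
Q02539	35	S	glyco	0.2	0.5
Q02539	41	S	glyco	0.45	0.5
Q02539	43	S	glyco	0.2	0.5
Q02539	48	S	glyco	0.2	0.5
Q02539	51	S	glyco	0.45	0.5
Q02539	52	S	glyco	0.7	0.5
Q02539	53	S	glyco	0.7	0.5
Q02539	60	S	glyco	0.2	0.5
Q02539	91	S	glyco	0.45	0.5
Q02539	94	T	glyco	0.45	0.5
Q02539	101	T	glyco	0.2	0.5
Q02539	103	S	glyco	0.2	0.5
Q02539	104	S	glyco	0.45	0.5
Q02539	106	S	glyco	0.45	0.5
Q02539	114	S	glyco	0.7	0.5
Q02539	115	S	glyco	0.2	0.5
Q02539	123	S	glyco	0.2	0.5
Q02539	135	S	glyco	0.2	0.5
Q02539	145	S	glyco	0.2	0.5
Q02539	148	S	glyco	0.2	0.5
Q02539	151	T	glyco	0.2	0.5
Q02539	161	T	glyco	0.7	0.5
Q02539	164	S	glyco	0.7	0.5
Q02539	165	S	glyco	0.7	0.5
Q02539	173	T	glyco	0.7	0.5
Q02539	182	S	glyco	0.45	0.5
Q02539	183	S	glyco	0.2	0.5
Q02539	199	T	glyco	0.7	0.5
Q02539	203	T	glyco	0.7	0.5
P16403	1	S	glyco	0.2	0.5
P16403	3	T	glyco	0.2	0.5
P16403	30	T	glyco	0.2	0.5
P16403	35	S	glyco	0.2	0.5
P16403	40	S	glyco	0.2	0.5
P16403	44	T	glyco	0.2	0.5
P16403	50	S	glyco	0.7	0.5
P16403	54	S	glyco	0.2	0.5
P16403	58	S	glyco	0.2	0.5
P16403	77	S	glyco	0.2	0.5
P16403	85	S	glyco	0.2	0.5
P16403	88	S	glyco	0.2	0.5
P16403	91	T	glyco	0.2	0.5
P16403	95	T	glyco	0.2	0.5
P16403	98	T	glyco	0.2	0.5
P16403	102	S	glyco	0.2	0.5
P16403	104	S	glyco	0.2	0.5
P16403	112	S	glyco	0.2	0.5
P16403	145	T	glyco	0.7	0.5
P16403	149	S	glyco	0.2	0.5
P16403	153	T	glyco	0.2	0.5
P16403	166	T	glyco	0.7	0.5
P16403	172	S	glyco	0.2	0.5
P16403	187	S	glyco	0.7	0.5
P16402	1	S	glyco	0.2	0.5
P16402	3	T	glyco	0.2	0.5
P16402	18	T	glyco	0.2	0.5
P16402	35	S	glyco	0.7	0.5
P16402	36	S	glyco	0.2	0.5
P16402	41	S	glyco	0.2	0.5
P16402	45	T	glyco	0.2	0.5
P16402	51	S	glyco	0.7	0.5
P16402	55	S	glyco	0.2	0.5
P16402	58	S	glyco	0.2	0.5
P16402	79	S	glyco	0.2	0.5
P16402	86	S	glyco	0.2	0.5
P16402	89	S	glyco	0.2	0.5
P16402	92	T	glyco	0.45	0.5
P16402	96	T	glyco	0.2	0.5
P16402	99	T	glyco	0.2	0.5
P16402	102	S	glyco	0.2	0.5
P16402	104	S	glyco	0.45	0.5
P16402	113	S	glyco	0.2	0.5
P16402	146	T	glyco	0.7	0.5
P16402	150	S	glyco	0.2	0.5
P16402	154	T	glyco	0.45	0.5
P16402	167	T	glyco	0.2	0.5
P16402	173	S	glyco	0.2	0.5
P16402	179	T	glyco	0.2	0.5
P16402	188	S	glyco	0.7	0.5
P16402	204	S	glyco	0.7	0.5
P10412	1	S	glyco	0.2	0.5
P10412	3	T	glyco	0.2	0.5
P10412	17	T	glyco	0.7	0.5
P10412	26	S	glyco	0.2	0.5
P10412	35	S	glyco	0.7	0.5
P10412	40	S	glyco	0.2	0.5
P10412	45	T	glyco	0.2	0.5
P10412	50	S	glyco	0.7	0.5
P10412	54	S	glyco	0.45	0.5
P10412	57	S	glyco	0.2	0.5
P10412	78	S	glyco	0.2	0.5
P10412	85	S	glyco	0.2	0.5
P10412	88	S	glyco	0.2	0.5
P10412	91	T	glyco	0.45	0.5
P10412	95	T	glyco	0.2	0.5
P10412	98	T	glyco	0.2	0.5
P10412	101	S	glyco	0.2	0.5
P10412	103	S	glyco	0.45	0.5
P10412	112	S	glyco	0.45	0.5
P10412	141	T	glyco	0.2	0.5
P10412	145	T	glyco	0.7	0.5
P10412	150	S	glyco	0.2	0.5
P10412	153	T	glyco	0.45	0.5
P10412	171	S	glyco	0.45	0.5
P10412	186	S	glyco	0.7	0.5
P10412	188	S	glyco	0.2	0.5
P10412	202	T	glyco	0.7	0.5
P16401	1	S	glyco	0.2	0.5
P16401	3	T	glyco	0.2	0.5
P16401	8	T	glyco	0.2	0.5
P16401	10	T	glyco	0.7	0.5
P16401	17	S	glyco	0.7	0.5
P16401	24	T	glyco	0.2	0.5
P16401	38	T	glyco	0.7	0.5
P16401	43	S	glyco	0.7	0.5
P16401	47	T	glyco	0.2	0.5
P16401	53	S	glyco	0.7	0.5
P16401	60	S	glyco	0.2	0.5
P16401	80	S	glyco	0.2	0.5
P16401	88	S	glyco	0.2	0.5
P16401	91	S	glyco	0.2	0.5
P16401	94	T	glyco	0.2	0.5
P16401	98	T	glyco	0.2	0.5
P16401	101	T	glyco	0.2	0.5
P16401	104	S	glyco	0.2	0.5
P16401	106	S	glyco	0.45	0.5
P16401	115	S	glyco	0.45	0.5
P16401	137	T	glyco	0.2	0.5
P16401	154	T	glyco	0.2	0.5
P16401	172	S	glyco	0.45	0.5
P16401	188	S	glyco	0.2	0.5
P07305	1	T	glyco	0.2	0.5
P07305	4	S	glyco	0.2	0.5
P07305	5	T	glyco	0.2	0.5
P07305	6	S	glyco	0.7	0.5
P07305	18	S	glyco	0.2	0.5
P07305	21	S	glyco	0.7	0.5
P07305	22	T	glyco	0.2	0.5
P07305	28	S	glyco	0.2	0.5
P07305	44	S	glyco	0.7	0.5
P07305	45	S	glyco	0.2	0.5
P07305	48	S	glyco	0.2	0.5
P07305	55	S	glyco	0.2	0.5
P07305	65	S	glyco	0.2	0.5
P07305	70	S	glyco	0.2	0.5
P07305	76	T	glyco	0.2	0.5
P07305	77	T	glyco	0.2	0.5
P07305	83	T	glyco	0.2	0.5
P07305	89	S	glyco	0.2	0.5
P07305	91	S	glyco	0.2	0.5
P07305	97	S	glyco	0.7	0.5
P07305	103	S	glyco	0.7	0.5
P07305	109	T	glyco	0.2	0.5
P07305	115	S	glyco	0.2	0.5
P07305	118	T	glyco	0.2	0.5
P07305	123	S	glyco	0.7	0.5
P07305	130	S	glyco	0.7	0.5
P07305	134	T	glyco	0.7	0.5
P07305	140	T	glyco	0.2	0.5
P07305	152	T	glyco	0.2	0.5
P07305	161	T	glyco	0.7	0.5
P07305	170	S	glyco	0.2	0.5
P07305	184	S	glyco	0.2	0.5
P07305	185	S	glyco	0.2	0.5
P22492	1	S	glyco	0.2	0.5
P22492	3	T	glyco	0.2	0.5
P22492	8	S	glyco	0.7	0.5
P22492	10	T	glyco	0.2	0.5
P22492	21	T	glyco	0.2	0.5
P22492	31	T	glyco	0.45	0.5
P22492	35	S	glyco	0.2	0.5
P22492	42	S	glyco	0.45	0.5
P22492	44	S	glyco	0.2	0.5
P22492	48	T	glyco	0.2	0.5
P22492	52	S	glyco	0.45	0.5
P22492	54	S	glyco	0.7	0.5
P22492	61	S	glyco	0.2	0.5
P22492	81	S	glyco	0.2	0.5
P22492	86	S	glyco	0.2	0.5
P22492	99	T	glyco	0.2	0.5
P22492	102	T	glyco	0.2	0.5
P22492	105	S	glyco	0.2	0.5
P22492	107	S	glyco	0.45	0.5
P22492	111	S	glyco	0.2	0.5
P22492	118	S	glyco	0.7	0.5
P22492	126	S	glyco	0.45	0.5
P22492	128	S	glyco	0.45	0.5
P22492	131	T	glyco	0.2	0.5
P22492	137	S	glyco	0.45	0.5
P22492	140	S	glyco	0.45	0.5
P22492	142	S	glyco	0.2	0.5
P22492	148	T	glyco	0.7	0.5
P22492	158	T	glyco	0.7	0.5
P22492	159	T	glyco	0.7	0.5
P22492	162	T	glyco	0.7	0.5
P22492	165	S	glyco	0.45	0.5
P22492	177	S	glyco	0.7	0.5
P22492	180	S	glyco	0.7	0.5
P22492	187	S	glyco	0.45	0.5
P22492	189	S	glyco	0.2	0.5
P22492	203	T	glyco	0.7	0.5
P22492	204	S	glyco	0.7	0.5
Q81ZA3	5	S	glyco	0.2	0.5
Q81ZA3	7	S	glyco	0.2	0.5
Q81ZA3	8	S	glyco	0.7	0.5
Q81ZA3	11	S	glyco	0.2	0.5
Q81ZA3	12	S	glyco	0.2	0.5
Q81ZA3	13	S	glyco	0.7	0.5
Q81ZA3	14	S	glyco	0.7	0.5
Q81ZA3	16	S	glyco	0.7	0.5
Q81ZA3	19	T	glyco	0.2	0.5
Q81ZA3	20	S	glyco	0.2	0.5
Q81ZA3	21	S	glyco	0.2	0.5
Q81ZA3	23	S	glyco	0.2	0.5
Q81ZA3	26	S	glyco	0.7	0.5
Q81ZA3	32	S	glyco	0.2	0.5
Q81ZA3	42	S	glyco	0.2	0.5
Q81ZA3	66	T	glyco	0.2	0.5
Q81ZA3	67	S	glyco	0.2	0.5
Q81ZA3	72	T	glyco	0.2	0.5
Q81ZA3	73	S	glyco	0.7	0.5
Q81ZA3	81	T	glyco	0.2	0.5
Q81ZA3	97	T	glyco	0.2	0.5
Q81ZA3	110	S	glyco	0.2	0.5
Q81ZA3	116	T	glyco	0.2	0.5
Q81ZA3	118	S	glyco	0.2	0.5
Q81ZA3	122	S	glyco	0.2	0.5
Q81ZA3	161	S	glyco	0.2	0.5
Q81ZA3	194	T	glyco	0.2	0.5
Q81ZA3	209	T	glyco	0.2	0.5
Q81ZA3	211	S	glyco	0.2	0.5
Q81ZA3	219	S	glyco	0.2	0.5
Q81ZA3	221	S	glyco	0.2	0.5
Q81ZA3	229	S	glyco	0.7	0.5
Q81ZA3	230	S	glyco	0.2	0.5
Q81ZA3	231	T	glyco	0.2	0.5
Q81ZA3	235	S	glyco	0.2	0.5
Q81ZA3	236	S	glyco	0.2	0.5
Q81ZA3	241	S	glyco	0.2	0.5
Q81ZA3	243	S	glyco	0.2	0.5
Q81ZA3	245	S	glyco	0.2	0.5
Q81ZA3	246	S	glyco	0.2	0.5
Q81ZA3	249	S	glyco	0.2	0.5
Q81ZA3	256	T	glyco	0.7	0.5
Q81ZA3	260	S	glyco	0.2	0.5
Q81ZA3	262	S	glyco	0.7	0.5
Q81ZA3	263	S	glyco	0.2	0.5
Q81ZA3	276	S	glyco	0.2	0.5
Q81ZA3	278	T	glyco	0.2	0.5
Q81ZA3	319	T	glyco	0.7	0.5
Q81ZA3	336	S	glyco	0.7	0.5
Q81ZA3	337	S	glyco	0.7	0.5
Q81ZA3	340	S	glyco	0.7	0.5
Q81ZA3	341	S	glyco	0.7	0.5
Q92522	2	S	glyco	0.2	0.5
Q92522	12	T	glyco	0.2	0.5
Q92522	13	T	glyco	0.2	0.5
Q92522	27	S	glyco	0.2	0.5
Q92522	31	S	glyco	0.2	0.5
Q92522	33	S	glyco	0.7	0.5
Q92522	39	S	glyco	0.2	0.5
Q92522	49	S	glyco	0.2	0.5
Q92522	55	T	glyco	0.2	0.5
Q92522	65	S	glyco	0.2	0.5
Q92522	66	S	glyco	0.2	0.5
Q92522	87	T	glyco	0.2	0.5
Q92522	92	S	glyco	0.2	0.5
Q92522	101	T	glyco	0.2	0.5
Q92522	113	S	glyco	0.2	0.5
Q92522	133	S	glyco	0.2	0.5
Q92522	154	S	glyco	0.2	0.5
Q92522	171	S	glyco	0.2	0.5
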