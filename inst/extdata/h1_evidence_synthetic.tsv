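seq_id	position	residue	source	provenance
Q02539	1	S	experimental	synthetic_curated
Q02539	35	S	experimental	synthetic_curated
Q02539	103	S	experimental	synthetic_curated
Q02539	151	T	experimental	synthetic_curated
Q02539	182	S	experimental	synthetic_curated
Q02539	183	S	experimental	synthetic_curated
P16403	1	S	experimental	synthetic_curated
P16403	30	T	experimental	synthetic_curated
P16403	172	S	experimental	synthetic_curated
P16402	18	T	experimental	synthetic_curated
P16402	188	S	experimental	synthetic_curated
P10412	17	T	experimental	synthetic_curated
P10412	35	S	experimental	synthetic_curated
P10412	145	T	experimental	synthetic_curated
P10412	171	S	experimental	synthetic_curated
P10412	186	S	experimental	synthetic_curated
P16401	17	S	experimental	synthetic_curated
P16401	137	T	experimental	synthetic_curated
P16401	154	T	experimental	synthetic_curated
P16401	172	S	experimental	synthetic_curated
P16401	188	S	experimental	synthetic_curated
P07305	123	S	experimental	synthetic_curated
P22492	158	T	experimental	synthetic_curated
P22492	159	T	experimental	synthetic_curated
P22492	177	S	experimental	synthetic_curated
Q92522	2	S	experimental	synthetic_curated
Q92522	31	S	experimental	synthetic_curated
Q92522	33	S	experimental	synthetic_curated
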