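gene_id	pH74_r1	pH74_LPS_r1	pH65_r1	pH65_LPS_r1	pH74_r2	pH74_LPS_r2	pH65_r2	pH65_LPS_r2
gene00001	28	12	49	3	45	9	54	2
gene00002	239	859	168	3192	228	629	175	4191
gene00003	117	148	98	139	145	161	138	110
gene00004	542	665	199	188	837	772	235	188
gene00005	146	658	131	90	126	612	124	140
gene00006	716	1723	745	2438	571	2272	500	2272
gene00007	573	1440	383	387	459	1341	339	426
gene00008	494	459	596	549	451	592	413	543
gene00009	117	20	130	136	112	30	125	122
gene00010	253	87	300	438	380	83	385	350
gene00011	35	8	43	7	37	10	40	7
gene00012	514	135	641	719	622	165	688	526
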