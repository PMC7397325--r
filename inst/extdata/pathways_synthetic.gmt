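AV	synthetic stand-in gene list (PW01)	G000001	G000002	G000003	G000004	G000005	G000006	G000007	G000008	G000009	G000010	G000011	G000012	G000013	G000014	G000015	G000016	G000017	G000018	G000019	G000020	G000021	G000022	G000023	G000024	G000025	G000026	G000027	G000028	G000029	G000030	G000031	G000032	G000033	G000034	G000035	G000036	G000037	G000038	G000039	G000040
AR-V	synthetic stand-in gene list (PW02)	G000041	G000042	G000043	G000044	G000045	G000046	G000047	G000048	G000049	G000050	G000051	G000052	G000053	G000054	G000055	G000056	G000057	G000058	G000059	G000060	G000061	G000062	G000063	G000064	G000065	G000066	G000067	G000068	G000069	G000070	G000071	G000072	G000073	G000074	G000075	G000076	G000077	G000078	G000079	G000080
PRF	synthetic stand-in gene list (PW03)	G000081	G000082	G000083	G000084	G000085	G000086	G000087	G000088	G000089	G000090	G000091	G000092	G000093	G000094	G000095	G000096	G000097	G000098	G000099	G000100	G000101	G000102	G000103	G000104	G000105	G000106	G000107	G000108	G000109	G000110	G000111	G000112	G000113	G000114	G000115	G000116	G000117	G000118	G000119	G000120
PTEN	synthetic stand-in gene list (PW04)	G000121	G000122	G000123	G000124	G000125	G000126	G000127	G000128	G000129	G000130	G000131	G000132	G000133	G000134	G000135	G000136	G000137	G000138	G000139	G000140	G000141	G000142	G000143	G000144	G000145	G000146	G000147	G000148	G000149	G000150	G000151	G000152	G000153	G000154	G000155	G000156	G000157	G000158	G000159	G000160
ES	synthetic stand-in gene list (PW05)	G000161	G000162	G000163	G000164	G000165	G000166	G000167	G000168	G000169	G000170	G000171	G000172	G000173	G000174	G000175	G000176	G000177	G000178	G000179	G000180	G000181	G000182	G000183	G000184	G000185	G000186	G000187	G000188	G000189	G000190	G000191	G000192	G000193	G000194	G000195	G000196	G000197	G000198	G000199	G000200
ERG	synthetic stand-in gene list (PW06)	G000201	G000202	G000203	G000204	G000205	G000206	G000207	G000208	G000209	G000210	G000211	G000212	G000213	G000214	G000215	G000216	G000217	G000218	G000219	G000220	G000221	G000222	G000223	G000224	G000225	G000226	G000227	G000228	G000229	G000230	G000231	G000232	G000233	G000234	G000235	G000236	G000237	G000238	G000239	G000240
AR	synthetic stand-in gene list (PW07)	G000241	G000242	G000243	G000244	G000245	G000246	G000247	G000248	G000249	G000250	G000251	G000252	G000253	G000254	G000255	G000256	G000257	G000258	G000259	G000260	G000261	G000262	G000263	G000264	G000265	G000266	G000267	G000268	G000269	G000270	G000271	G000272	G000273	G000274	G000275	G000276	G000277	G000278	G000279	G000280
FOXA1	synthetic stand-in gene list (PW08)	G000281	G000282	G000283	G000284	G000285	G000286	G000287	G000288	G000289	G000290	G000291	G000292	G000293	G000294	G000295	G000296	G000297	G000298	G000299	G000300	G000301	G000302	G000303	G000304	G000305	G000306	G000307	G000308	G000309	G000310	G000311	G000312	G000313	G000314	G000315	G000316	G000317	G000318	G000319	G000320
PRC	synthetic stand-in gene list (PW09)	G000321	G000322	G000323	G000324	G000325	G000326	G000327	G000328	G000329	G000330	G000331	G000332	G000333	G000334	G000335	G000336	G000337	G000338	G000339	G000340	G000341	G000342	G000343	G000344	G000345	G000346	G000347	G000348	G000349	G000350	G000351	G000352	G000353	G000354	G000355	G000356	G000357	G000358	G000359	G000360
PN	synthetic stand-in gene list (PW10)	G000361	G000362	G000363	G000364	G000365	G000366	G000367	G000368	G000369	G000370	G000371	G000372	G000373	G000374	G000375	G000376	G000377	G000378	G000379	G000380	G000381	G000382	G000383	G000384	G000385	G000386	G000387	G000388	G000389	G000390	G000391	G000392	G000393	G000394	G000395	G000396	G000397	G000398	G000399	G000400
MES	synthetic stand-in gene list (PW11)	G000401	G000402	G000403	G000404	G000405	G000406	G000407	G000408	G000409	G000410	G000411	G000412	G000413	G000414	G000415	G000416	G000417	G000418	G000419	G000420	G000421	G000422	G000423	G000424	G000425	G000426	G000427	G000428	G000429	G000430	G000431	G000432	G000433	G000434	G000435	G000436	G000437	G000438	G000439	G000440
RAS	synthetic stand-in gene list (PW12)	G000441	G000442	G000443	G000444	G000445	G000446	G000447	G000448	G000449	G000450	G000451	G000452	G000453	G000454	G000455	G000456	G000457	G000458	G000459	G000460	G000461	G000462	G000463	G000464	G000465	G000466	G000467	G000468	G000469	G000470	G000471	G000472	G000473	G000474	G000475	G000476	G000477	G000478	G000479	G000480
EZH2	synthetic stand-in gene list (PW13)	G000481	G000482	G000483	G000484	G000485	G000486	G000487	G000488	G000489	G000490	G000491	G000492	G000493	G000494	G000495	G000496	G000497	G000498	G000499	G000500	G000501	G000502	G000503	G000504	G000505	G000506	G000507	G000508	G000509	G000510	G000511	G000512	G000513	G000514	G000515	G000516	G000517	G000518	G000519	G000520
WNT	synthetic stand-in gene list (PW14)	G000521	G000522	G000523	G000524	G000525	G000526	G000527	G000528	G000529	G000530	G000531	G000532	G000533	G000534	G000535	G000536	G000537	G000538	G000539	G000540	G000541	G000542	G000543	G000544	G000545	G000546	G000547	G000548	G000549	G000550	G000551	G000552	G000553	G000554	G000555	G000556	G000557	G000558	G000559	G000560
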