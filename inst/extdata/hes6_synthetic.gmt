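HES6_synthetic	synthetic 222-gene HES6-controlled signature stand-in	G000001	G000002	G000003	G000004	G000005	G000006	G000007	G000008	G000009	G000010	G000011	G000012	G000013	G000014	G000015	G000016	G000017	G000018	G000019	G000020	G000021	G000022	G000023	G000024	G000025	G000026	G000027	G000028	G000029	G000030	G000031	G000032	G000033	G000034	G000035	G000036	G000037	G000038	G000039	G000040	G000121	G000122	G000123	G000124	G000125	G000126	G000127	G000128	G000129	G000130	G000131	G000132	G000133	G000134	G000135	G000136	G000137	G000138	G000139	G000140	G000141	G000142	G000143	G000144	G000145	G000146	G000147	G000148	G000149	G000150	G000151	G000152	G000153	G000154	G000155	G000156	G000157	G000158	G000159	G000160	G000241	G000242	G000243	G000244	G000245	G000246	G000247	G000248	G000249	G000250	G000251	G000252	G000253	G000254	G000255	G000256	G000257	G000258	G000259	G000260	G000261	G000262	G000263	G000264	G000265	G000266	G000267	G000268	G000269	G000270	G000271	G000272	G000273	G000274	G000275	G000276	G000277	G000278	G000279	G000280	G000361	G000362	G000363	G000364	G000365	G000366	G000367	G000368	G000369	G000370	G000371	G000372	G000373	G000374	G000375	G000376	G000377	G000378	G000379	G000380	G000381	G000382	G000383	G000384	G000385	G000386	G000387	G000388	G000389	G000390	G000391	G000392	G000393	G000394	G000395	G000396	G000397	G000398	G000399	G000400	G000481	G000482	G000483	G000484	G000485	G000486	G000487	G000488	G000489	G000490	G000491	G000492	G000493	G000494	G000495	G000496	G000497	G000498	G000499	G000500	G000501	G000502	G000503	G000504	G000505	G000506	G000507	G000508	G000509	G000510	G000511	G000512	G000513	G000514	G000515	G000516	G000517	G000518	G000519	G000520
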