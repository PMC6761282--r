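feature	S01	S02	S03	S04	S05	S06	S07	S08	S09	S10	S11	S12
miR-01	7034	1965	8392	9407	11617	6295	24212	15404	21853	49308	46439	37847
miR-02	34561	31748	32000	18419	12163	11311	6942	11018	6847	3116	5170	2993
miR-03	475	265	501	728	901	917	2498	1429	1701	2424	3343	2894
miR-04	3943	5213	7898	1282	2562	1873	3065	1327	2401	357	975	750
miR-05	1350	1035	902	1682	3294	1457	4911	4448	5397	15230	8837	8943
miR-06	16276	12848	26778	9547	10420	9610	2302	5511	6051	2908	2116	2415
miR-07	799	784	567	1494	2008	2087	4548	4218	3803	6443	8190	5097
miR-08	164	151	163	100	109	115	111	126	85	70	67	200
miR-09	494	380	321	260	314	310	345	537	190	339	316	294
miR-10	1322	931	1142	630	1001	1144	1162	1079	1437	870	1332	1080
miR-11	2030	1962	2047	1046	1000	1623	2709	1645	2052	1322	1167	1484
miR-12	651	596	409	629	744	876	1384	503	780	738	398	502
miR-13	3497	7905	14708	6092	6163	5337	4400	4093	10190	6392	5565	4770
miR-14	181	97	258	116	137	97	162	211	257	136	147	121
miR-15	100	128	102	101	92	147	133	83	131	52	149	92
miR-16	887	493	729	466	988	440	1070	1201	971	694	908	955
miR-17	1306	1153	1714	1514	2812	1008	1791	1460	2202	3088	767	1536
miR-18	11368	11551	7440	9674	8527	7857	5781	8867	14166	12471	4749	10959
miR-19	1367	1727	2201	1871	1742	777	2126	1848	2970	1385	2666	1053
miR-20	269	196	412	272	288	229	303	217	555	222	315	288
miR-21	1220	702	988	975	945	549	1415	776	1361	1087	624	533
miR-22	986	985	1019	553	865	1521	1243	766	1597	821	741	812
miR-23	497	761	479	576	792	580	711	516	531	705	623	562
miR-24	20321	20364	23993	34472	16217	13014	38362	42242	17194	12040	21161	15129
miR-25	543	575	681	479	597	713	1039	788	590	562	576	414
miR-26	251	304	176	177	314	216	287	216	322	382	344	245
miR-27	157	384	537	450	527	327	368	564	433	353	423	264
miR-28	453	552	540	339	664	580	440	607	368	714	617	502
miR-29	5755	7653	7934	12965	9823	6992	18448	11478	4998	5982	7549	7317
miR-30	418	438	641	589	819	160	822	584	503	529	330	290
miR-31	1554	2691	2106	1780	2936	1537	3070	2738	3273	2466	3825	772
miR-32	8415	5840	9055	10066	11939	10999	12786	10544	12517	13585	11666	12161
miR-33	1052	939	1821	2216	1599	2934	2028	1054	1414	862	1716	787
miR-34	424	132	263	311	363	269	450	304	592	316	449	211
miR-35	1024	1422	2147	2267	1794	2137	1979	1981	2472	1464	1268	1433
miR-36	5128	5654	4831	6642	6146	5249	8995	10842	5270	7803	5621	3856
miR-37	2056	2989	3434	1651	2465	3886	4160	2492	3664	1712	3269	3499
miR-38	1965	3890	4377	2490	3407	2680	3780	5644	5501	3746	2176	1249
miR-39	629	350	892	793	606	478	886	826	433	617	873	356
miR-40	5076	5049	4275	4154	3236	4158	5980	5685	6690	5438	5170	5381
miR-41	682	466	506	377	1001	493	703	936	973	445	1098	405
miR-42	6175	1916	5574	3414	5323	6092	14777	3077	6116	7722	6994	3507
miR-43	355	230	182	139	116	272	319	162	315	224	169	129
miR-44	3753	7951	5412	7088	4268	7537	8994	11675	12809	11051	7313	5127
miR-45	28424	11312	6804	11001	17206	20300	17160	19256	28133	17201	11255	17362
miR-46	24	15	23	13	18	21	50	33	29	28	26	17
miR-47	2554	1496	1062	995	1928	1421	1987	1979	3158	1990	1915	1471
miR-48	143	104	120	145	111	96	210	139	198	201	84	74
miR-49	14005	6000	10478	6601	16484	10045	12597	11522	5344	10456	9789	6105
miR-50	3248	6988	4680	3887	3418	5570	7573	5743	7238	4688	3766	4334
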