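id	R.frontal	L.frontal	R.temporal	L.temporal	R.parietal	L.parietal	R.occipital	L.occipital	R.limbic	L.limbic	R.sublobar	L.sublobar	R.brainstem	L.brainstem	R.cerebellum	L.cerebellum
C01	69.0185	70.1007	48.72	40.762	37.894	38.4597	26.0769	22.0591	15.3748	15.9762	22.08	22.868	1.9369	1.2506	48.1618	51.592
C02	91.4921	82.1122	49.8318	49.8512	39.7353	40.7113	25.5562	26.741	17.3206	16.922	27.3762	25.1839	1.3193	1.5809	57.1011	55.5216
C03	60.194	67.7121	42.2226	41.356	33.0269	34.7157	23.1953	19.5339	12.705	12.5394	19.7688	18.4382	2.0107	1.2206	43.2733	47.0967
C04	76.8568	77.3603	47.6135	45.3226	43.5984	36.771	28.9684	27.1992	16.2204	15.3619	25.2935	21.075	1.9422	1.9423	56.0115	54.6406
C05	69.3901	78.1033	49.1714	50.9891	44.3244	38.57	25.1676	25.6974	16.7214	16.4445	27.5703	25.0517	1.6771	1.5613	49.6003	52.8394
C06	62.5642	61.983	35.8964	41.6852	35.945	28.7363	21.2827	21.3258	15.2255	11.9862	20.5538	17.4446	1.377	1.7968	43.7559	43.2795
C07	81.7346	83.9419	48.91	44.4005	46.7149	40.9619	25.113	27.8329	17.1938	16.5194	25.4059	25.2489	2.0358	1.4227	56.6545	50.9518
C08	69.4665	81.8289	40.1452	39.5004	36.3972	40.4175	22.9839	25.927	14.989	12.9761	23.0287	21.8872	1.7592	1.9677	44.4687	51.1417
C09	61.3343	54.97	43.0386	30.0566	36.8951	29.4152	21.708	21.6669	12.9957	10.2929	18.477	17.8624	1.4942	1.151	43.0722	38.2427
C10	79.9698	79.767	46.4068	45.188	41.0758	36.6712	20.8579	23.8033	14.1516	15.1202	24.8132	25.1403	1.6006	1.565	49.4162	54.4014
C11	77.9505	83.1113	54.6798	44.8624	43.2449	41.7585	29.049	24.631	16.2562	15.6144	26.2407	21.3834	1.4606	1.4402	61.4199	51.9173
C12	74.0352	72.2459	46.4617	41.8881	42.1868	40.2258	27.8399	25.8468	14.6823	15.1939	24.6194	24.8873	1.7138	1.2012	57.9794	63.0268
C13	54.4516	56.0017	35.2639	34.849	32.2007	31.3878	17.1986	18.5291	10.2698	10.248	18.8016	18.5711	1.431	1.1547	37.154	41.356
C14	73.8716	73.7842	46.4757	44.8708	38.7602	38.67	25.175	20.1911	14.1337	14.3594	22.4816	22.679	1.8945	1.5263	50.6298	51.409
C15	71.6282	72.943	42.3533	40.9881	33.0268	36.375	23.2849	22.5779	14.5135	11.8759	24.4589	20.9667	1.765	1.1987	46.1253	52.345
C16	67.942	75.3351	43.9408	40.0444	34.2315	37.5262	17.8397	22.2608	13.5238	12.6893	21.4093	21.5732	1.5441	1.4445	44.0954	49.2545
C17	81.1777	77.5801	40.7718	44.669	29.9631	35.9591	23.8243	23.3967	16.5303	14.9644	27.8744	20.6349	1.3249	1.7197	42.5614	51.4568
C18	94.0475	91.1561	59.7731	56.5333	46.9388	51.3845	30.0939	30.3176	16.5954	17.8461	32.2081	26.0098	1.4791	1.9985	63.593	62.7407
C19	94.8051	94.3743	55.0558	54.284	50.58	49.131	26.0404	28.6653	18.0172	17.9414	25.4108	28.9377	1.7287	1.434	68.5998	56.7118
C20	87.2433	91.2621	51.1936	45.1698	41.631	47.1632	27.2451	26.6154	18.6648	17.3528	26.8144	29.1914	2.2629	1.6361	58.5443	59.7589
C21	92.3372	99.3476	52.5789	53.824	43.9144	44.7093	28.55	29.3653	17.9275	17.8053	28.9674	28.6638	2.1271	1.5047	61.964	62.3309
C22	89.2767	65.3714	49.1144	46.6997	44.6955	39.3187	26.2912	25.5219	15.5098	13.7672	24.2864	24.7461	1.6977	1.5123	48.7174	57.2159
C23	93.0754	90.7458	48.3808	45.6108	45.407	44.2837	26.3193	30.0965	17.3032	16.0719	30.7541	26.63	1.6585	1.3765	53.1989	57.0609
M01	69.0741	74.8634	37.5942	40.7011	28.5353	33.433	21.6945	19.8726	15.3006	10.2784	17.982	17.3165	1.9234	2.1272	38.2837	43.1339
M02	77.8743	78.4756	48.8151	38.635	41.2713	37.7339	21.7243	21.5787	16.4713	14.4894	25.2293	25.0782	1.8971	2.0232	50.3719	44.5682
M03	85.4638	85.9868	51.2975	46.9056	40.7005	41.1841	23.7906	25.7733	14.1274	15.0796	24.5355	22.4846	1.8135	1.503	51.448	49.1211
M04	83.559	80.1881	51.0555	43.1358	40.2302	39.3051	22.9172	22.4989	16.5623	14.317	26.0081	22.8172	2.3994	1.485	52.5729	52.559
M05	91.4777	87.4883	57.749	46.8655	42.3898	42.503	26.2597	29.3208	17.6915	16.6482	27.3727	25.0929	1.7169	1.3845	51.5819	58.1575
M06	75.1139	71.8359	43.539	35.9695	34.5413	30.314	24.2173	20.853	13.1827	12.1946	18.582	20.0651	1.4852	1.6208	48.4578	41.4812
M07	80.1514	72.8283	48.6162	46.2706	33.3442	32.5315	23.859	20.0501	13.1617	14.7657	22.0664	22.3001	2.2085	2.0676	45.1793	47.9924
M08	92.0335	79.4448	53.803	45.0378	41.6353	41.2152	25.4688	26.2678	15.2211	15.6231	25.6	21.5994	2.0877	1.5154	53.1554	55.5711
M09	97.035	81.6433	46.385	48.2363	43.7329	44.3245	26.0657	26.0334	15.2726	15.7862	25.608	24.3868	1.9181	2.0099	52.0554	51.53
M10	84.1709	87.5659	47.5245	44.4009	39.8694	38.6147	29.598	24.8862	15.87	16.0039	21.0204	24.4831	1.9648	1.7675	54.5653	53.8809
M11	80.5029	83.1114	55.7062	44.677	44.364	38.586	25.2222	26.7735	14.1579	15.5986	23.8029	24.3003	2.2019	1.6232	53.5343	53.4272
M12	89.6724	89.3576	53.7238	47.3699	41.7695	42.2862	27.4926	24.9533	15.2049	15.8909	25.3579	26.3616	1.9593	1.1502	55.9048	52.0538
M13	86.5769	80.1973	59.7837	46.4672	39.4093	42.0274	26.3919	24.8502	16.5189	16.1898	24.7378	24.6737	1.8841	1.7012	51.7356	52.1786
M14	84.0708	79.3904	43.137	45.8431	41.1687	38.2314	25.6039	22.1994	15.0537	15.1682	24.6574	24.4726	1.6403	1.4855	45.7042	50.1564
M15	80.3259	86.8936	48.8511	46.3854	35.581	38.0846	25.5573	24.9707	15.1795	12.2074	20.0651	23.415	1.9272	1.3222	49.0061	47.2711
M16	92.1824	85.504	54.6234	44.2763	43.4705	45.345	23.8222	24.2176	15.7433	14.9324	25.2651	23.342	2.112	1.4758	46.0244	52.0063
M17	77.8056	85.7865	50.4256	44.7848	37.0157	38.089	23.8672	22.8627	14.3696	14.7491	22.9982	22.8085	1.6581	1.6782	47.1329	48.1619
M18	89.5737	85.7956	50.4792	52.7276	42.8541	34.2947	24.2111	26.9114	18.0117	16.256	22.9304	20.9058	2.3708	1.1872	55.506	50.1774
M19	86.561	96.2805	58.7612	47.2216	42.538	44.1482	27.7132	26.9997	18.0612	16.4619	28.1888	27.4139	1.9901	1.5124	52.6817	55.7523
M20	98.4276	90.036	55.6995	46.2661	43.8449	46.1683	26.7158	29.1488	18.7993	17.517	27.5936	25.1208	1.8492	1.3376	55.9245	53.8059
M21	85.0664	86.2012	58.9961	46.0018	45.1269	43.0382	24.1033	25.9327	16.0555	15.9891	27.281	24.7074	1.8707	1.8052	50.3991	52.6036
M22	88.4611	89.7962	54.6794	45.9642	46.8385	40.662	27.4342	26.3633	16.8904	15.7645	26.0138	25.7378	2.4995	1.8026	56.495	54.0434
M23	88.1921	78.3797	53.6278	44.4031	36.9429	38.1321	24.3246	25.4044	13.8489	15.3093	25.0117	23.6657	1.9437	1.9617	52.4094	49.1801
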