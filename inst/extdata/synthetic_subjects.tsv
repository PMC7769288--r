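id	group	age	sex	tiv_ml
C01	control	32.6444913572632	F	1331.56199264721
C02	control	21.021769142244	F	1365.74189555441
C03	control	42.4455516650341	F	1156.09194538905
C04	control	21.5900121512823	F	1344.18600285715
C05	control	23.7169706183486	F	1325.36697702841
C06	control	61.1036674696952	F	1286.69669181931
C07	control	24.6328274309635	F	1406.38955191677
C08	control	33.1789503847249	F	1243.84535012693
C09	control	57.9893652596511	F	1212.69959980713
C10	control	26.175080455374	F	1291.08467731958
C11	control	28.3547427523881	F	1409.46408753068
C12	control	39.5115114147775	F	1479.79545359039
C13	control	59.1016848902218	F	1149.65237003658
C14	control	56.7437584111467	F	1467.15510979127
C15	control	51.8274746951647	F	1394.75553318221
C16	control	45.0948003027588	F	1321.03891418376
C17	control	41.2341525075026	F	1355.77119234892
C18	control	34.8856617682613	M	1689.91084785259
C19	control	27.6217304547317	M	1624.5546611432
C20	control	41.1656302423216	M	1668.19456484751
C21	control	29.5559289772063	M	1620.14666313606
C22	control	49.575430279132	M	1509.52447960571
C23	control	36.2790971766226	M	1599.6209191997
M01	meditator	47.0288759144023	F	1151.3218631672
M02	meditator	49.813985651359	F	1458.0058181492
M03	meditator	38.8730326546356	F	1442.38565561464
M04	meditator	38.9004720747471	F	1391.98526802605
M05	meditator	29.5894967867061	F	1448.98705740008
M06	meditator	60.4335450036451	F	1347.00060999224
M07	meditator	43.5006169388071	F	1288.14975173723
M08	meditator	32.3599079274572	F	1419.97341572856
M09	meditator	34.9584696209058	F	1385.9192348086
M10	meditator	36.288484712597	F	1424.26264281777
M11	meditator	30.2525927997194	F	1354.33549458173
M12	meditator	23.1363631356508	F	1413.87933206426
M13	meditator	41.8445469103754	F	1518.78705952296
M14	meditator	42.3414793512784	F	1376.01650977954
M15	meditator	30.9088663668372	F	1285.09871320677
M16	meditator	55.1768518737517	F	1603.96930572073
M17	meditator	38.6023464021273	F	1357.87970477926
M18	meditator	29.0387902166694	M	1404.97926289424
M19	meditator	48.2537828246132	M	1653.87114903085
M20	meditator	55.1577895958908	M	1769.35148168281
M21	meditator	30.471063609235	M	1520.90317794977
M22	meditator	36.3497564806603	M	1492.47393999123
M23	meditator	53.1135194711387	M	1539.21248776281
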