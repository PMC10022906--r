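synthetic_block_A	synthetic fixture set	G0001	G0002	G0003	G0004	G0005	G0006	G0007	G0008	G0009	G0010	G0011	G0012	G0013	G0014	G0015	G0016	G0017	G0018	G0019	G0020	G0021	G0022	G0023	G0024	G0025	G0026	G0027	G0028	G0029	G0030	G0031	G0032	G0033	G0034	G0035	G0036	G0037	G0038	G0039	G0040	G0041	G0042	G0043	G0044	G0045	G0046	G0047	G0048	G0049	G0050	G0051	G0052	G0053	G0054	G0055	G0056	G0057	G0058	G0059	G0060
synthetic_block_B	synthetic fixture set	G0061	G0062	G0063	G0064	G0065	G0066	G0067	G0068	G0069	G0070	G0071	G0072	G0073	G0074	G0075	G0076	G0077	G0078	G0079	G0080	G0081	G0082	G0083	G0084	G0085	G0086	G0087	G0088	G0089	G0090	G0091	G0092	G0093	G0094	G0095	G0096	G0097	G0098	G0099	G0100	G0101	G0102	G0103	G0104	G0105	G0106	G0107	G0108	G0109	G0110	G0111	G0112	G0113	G0114	G0115	G0116	G0117	G0118	G0119	G0120
synthetic_block_C	synthetic fixture set	G0121	G0122	G0123	G0124	G0125	G0126	G0127	G0128	G0129	G0130	G0131	G0132	G0133	G0134	G0135	G0136	G0137	G0138	G0139	G0140	G0141	G0142	G0143	G0144	G0145	G0146	G0147	G0148	G0149	G0150	G0151	G0152	G0153	G0154	G0155	G0156	G0157	G0158	G0159	G0160
synthetic_block_D	synthetic fixture set	G0161	G0162	G0163	G0164	G0165	G0166	G0167	G0168	G0169	G0170	G0171	G0172	G0173	G0174	G0175	G0176	G0177	G0178	G0179	G0180	G0181	G0182	G0183	G0184	G0185	G0186	G0187	G0188	G0189	G0190	G0191	G0192	G0193	G0194	G0195	G0196	G0197	G0198	G0199	G0200	G0201	G0202	G0203	G0204	G0205	G0206	G0207	G0208	G0209	G0210	G0211	G0212	G0213	G0214	G0215	G0216	G0217	G0218	G0219	G0220
synthetic_block_E	synthetic fixture set	G0221	G0222	G0223	G0224	G0225	G0226	G0227	G0228	G0229	G0230	G0231	G0232	G0233	G0234	G0235	G0236	G0237	G0238	G0239	G0240	G0241	G0242	G0243	G0244	G0245	G0246	G0247	G0248	G0249	G0250	G0251	G0252	G0253	G0254	G0255	G0256	G0257	G0258	G0259	G0260
synthetic_sparse_F	synthetic fixture set	G0300	G0330	G0360	G0390	G0420	G0450	G0480	G0510	G0540	G0570	G0600	G0630	G0660	G0690	G0720	G0750	G0780	G0810	G0840	G0870	G0900	G0930	G0960	G0990	G1020	G1050	G1080	G1110	G1140	G1170	G1200	G1230	G1260	G1290	G1320	G1350	G1380	G1410	G1440	G1470	G1500	G1530	G1560	G1590	G1620	G1650	G1680	G1710	G1740	G1770	G1800
synthetic_sparse_G	synthetic fixture set	G0310	G0355	G0400	G0445	G0490	G0535	G0580	G0625	G0670	G0715	G0760	G0805	G0850	G0895	G0940	G0985	G1030	G1075	G1120	G1165	G1210	G1255	G1300	G1345	G1390	G1435	G1480	G1525	G1570	G1615	G1660	G1705	G1750	G1795
synthetic_wide_H	synthetic fixture set	G0002	G0009	G0016	G0023	G0030	G0037	G0044	G0051	G0058	G0065	G0072	G0079	G0086	G0093	G0100	G0107	G0114	G0121	G0128	G0135	G0142	G0149	G0156	G0163	G0170	G0177	G0184	G0191	G0198	G0205	G0212	G0219	G0226	G0233	G0240	G0247	G0254	G0261	G0268	G0275	G0282	G0289	G0296	G0303	G0310	G0317	G0324	G0331	G0338	G0345	G0352	G0359	G0366	G0373	G0380	G0387	G0394	G0401	G0408	G0415	G0422	G0429	G0436	G0443	G0450	G0457	G0464	G0471	G0478	G0485	G0492	G0499	G0506	G0513	G0520	G0527	G0534	G0541	G0548	G0555	G0562	G0569	G0576	G0583	G0590	G0597	G0604	G0611	G0618	G0625	G0632	G0639	G0646	G0653	G0660	G0667	G0674	G0681	G0688	G0695	G0702	G0709	G0716	G0723	G0730	G0737	G0744	G0751	G0758	G0765	G0772	G0779	G0786	G0793	G0800	G0807	G0814	G0821	G0828	G0835	G0842	G0849	G0856	G0863	G0870	G0877	G0884	G0891	G0898	G0905	G0912	G0919	G0926	G0933	G0940	G0947	G0954	G0961	G0968	G0975	G0982	G0989	G0996	G1003	G1010	G1017	G1024	G1031	G1038	G1045	G1052	G1059	G1066	G1073	G1080	G1087	G1094	G1101	G1108	G1115	G1122	G1129	G1136	G1143	G1150	G1157	G1164	G1171	G1178	G1185	G1192	G1199	G1206	G1213	G1220	G1227	G1234	G1241	G1248	G1255	G1262	G1269	G1276	G1283	G1290	G1297	G1304	G1311	G1318	G1325	G1332	G1339	G1346	G1353	G1360	G1367	G1374	G1381	G1388	G1395	G1402	G1409	G1416	G1423	G1430	G1437	G1444	G1451	G1458	G1465	G1472	G1479	G1486	G1493	G1500	G1507	G1514	G1521	G1528	G1535	G1542	G1549	G1556	G1563	G1570	G1577	G1584	G1591	G1598	G1605	G1612	G1619	G1626	G1633	G1640	G1647	G1654	G1661	G1668	G1675	G1682	G1689	G1696	G1703	G1710	G1717	G1724	G1731	G1738	G1745	G1752	G1759	G1766	G1773	G1780	G1787	G1794	G1801	G1808	G1815	G1822
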