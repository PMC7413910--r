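name	family	precursor_pufa	position	acid_formula	mz_precursor	mz_fragment	rt_min	drift_ms	ccs_A2	lod_nM	lloq_nM	uloq_nM	r2	quantifier	lloq_at_cal_limit	uloq_at_cal_limit	unresolved_with
9,10-DiHOME	dihydroxy	LA	9	C18H34O4	481.3430	369.2178	9.06	27.11	216.8	0.6	1.5	292	0.9867	precursor	FALSE	FALSE	NA
12,13-DiHOME	dihydroxy	LA	12	C18H34O4	481.3430	351.2436	8.63	27.18	217.4	0.8	2.0	402	0.9957	precursor	FALSE	FALSE	NA
9,10-DiHODE	dihydroxy	ALA	9	C18H32O4	479.3273	369.2178	7.74	27.06	216.4	0.5	0.5	1256	0.9987	fragment	FALSE	TRUE	NA
12,13-DiHODE	dihydroxy	ALA	12	C18H32O4	479.3273	351.2436	7.40	26.38	211.0	0.2	0.9	434	0.9816	fragment	FALSE	TRUE	NA
15,16-DiHODE	dihydroxy	ALA	15	C18H32O4	479.3273	391.2749	7.49	26.20	209.6	0.6	1.4	1435	0.9895	fragment	FALSE	TRUE	NA
5,6-DiHETrE	dihydroxy	ARA	5	C20H34O4	505.3430	313.1552	12.34	27.50	219.6	4.7	12	1183	0.9958	precursor	FALSE	TRUE	NA
8,9-DiHETrE	dihydroxy	ARA	8	C20H34O4	505.3430	295.1810	11.14	27.79	221.9	0.9	2.3	467	0.9873	precursor	FALSE	FALSE	NA
11,12-DiHETrE	dihydroxy	ARA	11	C20H34O4	505.3430	335.2123	10.28	27.94	223.1	1.5	3.7	749	0.9966	precursor	FALSE	FALSE	NA
14,15-DiHETrE	dihydroxy	ARA	14	C20H34O4	505.3430	375.2436	9.48	27.57	220.2	2.4	5.9	1176	0.9950	precursor	FALSE	TRUE	NA
5,6-DiHETE	dihydroxy	EPA	5	C20H32O4	503.3274	313.1552	10.02	27.08	216.3	0.2	0.3	16	0.9743	precursor	FALSE	TRUE	NA
8,9-DiHETE	dihydroxy	EPA	8	C20H32O4	503.3274	295.1810	9.17	27.41	218.9	4.0	7.9	396	0.9974	precursor	FALSE	FALSE	NA
11,12-DiHETE	dihydroxy	EPA	11	C20H32O4	503.3274	335.2123	8.81	27.54	220.0	1.0	9.9	497	0.9780	precursor	FALSE	FALSE	NA
14,15-DiHETE	dihydroxy	EPA	14	C20H32O4	503.3274	375.2436	8.36	27.27	217.8	7.0	14	701	0.9990	precursor	FALSE	FALSE	NA
17,18-DiHETE	dihydroxy	EPA	17	C20H32O4	503.3274	415.2749	7.98	26.66	212.9	1.8	4.6	914	0.9930	precursor	FALSE	FALSE	NA
10,11-DiHDPE	dihydroxy	DHA	10	C22H34O4	529.3430	321.1967	11.13	28.33	226.0	1.2	6.2	3083	0.9986	precursor	FALSE	TRUE	NA
13,14-DiHDPE	dihydroxy	DHA	13	C22H34O4	529.3430	361.2280	10.63	28.19	224.9	0.9	4.3	2161	0.9959	precursor	FALSE	TRUE	NA
16,17-DiHDPE	dihydroxy	DHA	16	C22H34O4	529.3430	401.2593	10.23	28.05	223.7	0.7	3.4	1710	0.9963	precursor	FALSE	TRUE	NA
19,20-DiHDPE	dihydroxy	DHA	19	C22H34O4	529.3430	441.2906	9.62	27.60	220.2	7.1	7.1	1419	0.9956	precursor	TRUE	TRUE	NA
9(10)-EpOME	epoxy	LA	9	C18H32O3	463.3325	339.2073	15.89	26.71	213.8	0.8	3.8	376	0.9935	precursor	FALSE	FALSE	NA
12(13)-EpOME	epoxy	LA	12	C18H32O3	463.3325	363.2436	15.38	26.66	213.4	0.7	3.6	359	0.9949	precursor	FALSE	FALSE	NA
9(10)-EpODE	epoxy	ALA	9	C18H30O3	461.3168	339.2073	13.19	26.41	211.5	1.1	5.4	535	0.9984	precursor	FALSE	FALSE	NA
12(13)-EpODE	epoxy	ALA	12	C18H30O3	461.3168	363.2436	12.79	26.24	210.1	0.5	1.2	243	0.9937	precursor	FALSE	FALSE	NA
15(16)-EpODE	epoxy	ALA	15	C18H30O3	461.3168	389.2593	12.39	26.15	209.4	1.5	3.7	740	0.9958	precursor	FALSE	FALSE	NA
5(6)-EpETrE	epoxy	ARA	5	C20H32O3	487.3325	283.1447	18.95	27.18	217.3	6.3	63	626	0.9324	precursor	FALSE	TRUE	NA
8(9)-EpETrE	epoxy	ARA	8	C20H32O3	487.3325	307.1810	18.27	27.18	217.3	3.6	14	357	0.9991	precursor	FALSE	TRUE	NA
11(12)-EpETrE	epoxy	ARA	11	C20H32O3	487.3325	347.2123	17.79	27.24	217.8	6.2	25	615	0.9992	precursor	FALSE	TRUE	NA
14(15)-EpETrE	epoxy	ARA	14	C20H32O3	487.3325	333.1967	16.35	26.98	215.7	0.4	2.0	195	0.9952	precursor	FALSE	FALSE	NA
8(9)-EpETE	epoxy	EPA	8	C20H30O3	485.3168	307.1810	14.85	26.81	214.4	1.7	4.2	833	0.9874	precursor	FALSE	FALSE	NA
11(12)-EpETE	epoxy	EPA	11	C20H30O3	485.3168	347.2123	14.51	26.66	213.2	2.2	5.5	552	0.9934	fragment	FALSE	FALSE	NA
14(15)-EpETE	epoxy	EPA	14	C20H30O3	485.3168	387.2436	14.20	26.75	213.9	2.7	2.7	1347	0.9594	precursor	TRUE	FALSE	NA
17(18)-EpETE	epoxy	EPA	17	C20H30O3	485.3168	413.2593	13.17	26.65	213.1	3.9	3.9	968	0.9988	precursor	TRUE	FALSE	NA
10(11)-EpDPE	epoxy	DHA	10	C22H32O3	511.3325	363.2073	18.45	27.79	221.9	1.8	4.6	919	0.9717	precursor	FALSE	FALSE	NA
13(14)-EpDPE	epoxy	DHA	13	C22H32O3	511.3325	402.2307	18.16	27.76	221.6	1.2	3.0	302	0.9792	precursor	FALSE	FALSE	NA
16(17)-EpDPE	epoxy	DHA	16	C22H32O3	511.3325	413.2593	17.85	27.68	221.0	1.3	3.3	662	0.9985	precursor	FALSE	FALSE	NA
19(20)-EpDPE	epoxy	DHA	19	C22H32O3	511.3325	399.2436	16.65	27.61	220.4	2.8	7.0	1119	0.9874	precursor	FALSE	FALSE	NA
9-HODE	hydroxy	LA	9	C18H32O3	463.3325	339.2064	13.33	26.80	214.5	1.0	1.0	100	0.9730	precursor	TRUE	FALSE	NA
13-HODE	hydroxy	LA	13	C18H32O3	463.3325	363.2449	12.95	26.81	214.6	1.0	1.0	100	0.9574	precursor	TRUE	FALSE	NA
5-HETE	hydroxy	ARA	5	C20H32O3	487.3325	283.1596	17.06	27.07	216.4	10.0	20	500	0.9969	precursor	FALSE	TRUE	NA
8-HETE	hydroxy	ARA	8	C20H32O3	487.3325	295.1765	15.61	27.24	217.8	2.0	10	500	0.9438	precursor	FALSE	TRUE	NA
9-HETE	hydroxy	ARA	9	C20H32O3	487.3325	335.2133	14.99	27.37	218.8	2.0	10	500	0.9839	precursor	FALSE	TRUE	NA
11-HETE	hydroxy	ARA	11	C20H32O3	487.3325	345.1758	15.95	27.28	218.1	1.0	2.0	500	0.9304	precursor	FALSE	TRUE	NA
12-HETE	hydroxy	ARA	12	C20H32O3	487.3325	347.2091	15.33	27.50	219.8	2.0	10	500	0.9829	precursor	FALSE	TRUE	NA
15-HETE	hydroxy	ARA	15	C20H32O3	487.3325	363.3346	14.03	27.14	217.0	2.0	10	500	0.9751	precursor	FALSE	TRUE	NA
20-HETE	hydroxy	ARA	20	C20H32O3	487.3325	333.1954	11.93	26.74	213.8	2.0	10	500	0.9881	precursor	FALSE	TRUE	NA
5-HEPE	hydroxy	EPA	5	C20H30O3	485.3168	283.1582	13.82	26.45	211.5	2.0	10	500	0.9979	precursor	FALSE	TRUE	NA
8-HEPE	hydroxy	EPA	8	C20H30O3	485.3168	295.1815	12.48	26.82	214.4	1.0	2.0	500	0.8995	precursor	FALSE	TRUE	12-HEPE
12-HEPE	hydroxy	EPA	12	C20H30O3	485.3168	375.2058	12.48	27.15	217.1	1.0	2.0	500	0.9961	precursor	FALSE	TRUE	8-HEPE
15-HEPE	hydroxy	EPA	15	C20H30O3	485.3168	333.1957	11.90	26.74	213.8	1.0	2.0	500	0.9805	precursor	FALSE	TRUE	NA
18-HEPE	hydroxy	EPA	18	C20H30O3	485.3168	439.3329	10.95	25.98	207.7	1.0	1.0	500	0.9908	precursor	TRUE	TRUE	NA
7-HDHA	hydroxy	DHA	7	C22H32O3	511.3325	280.1516	16.72	27.38	218.6	1.0	2.0	500	0.9632	precursor	FALSE	TRUE	NA
11-HDHA	hydroxy	DHA	11	C22H32O3	511.3325	361.1898	16.21	27.91	222.8	1.0	1.0	500	0.9985	precursor	TRUE	TRUE	NA
14-HDHA	hydroxy	DHA	14	C22H32O3	511.3325	401.2270	15.67	27.83	222.2	2.0	10	500	0.9842	precursor	FALSE	TRUE	NA
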