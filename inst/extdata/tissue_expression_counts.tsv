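tissue_id	na	negative	weak	medium	strong	express	pct_na	pct_negative	pct_weak	pct_medium	pct_strong	pct_express	name
T1	6	977	685	284	48	1017	0.3	48.9	34.2	14.2	2.4	50.9	External acoustic meatus
T2	28	1248	538	166	20	724	1.4	62.4	26.9	8.3	1.0	36.2	Middle ear ossicles
T3	7	1090	749	136	18	903	0.3	54.5	37.5	6.8	0.9	45.1	Middle ear tympanic membrane
T4	4	868	757	305	66	1128	0.2	43.4	37.9	15.2	3.3	56.4	Middle ear mesenchyme
T5	10	1277	449	205	59	713	0.5	63.9	22.4	10.2	3.0	35.6	Otic capsule
T6	8	905	752	290	45	1087	0.4	45.2	37.6	14.5	2.2	54.4	Inner ear mesenchyme
T7	5	892	739	288	76	1103	0.2	44.6	37.0	14.4	3.8	55.1	Stato-acoustic ganglion
T8	1	1132	664	178	25	867	0.1	56.6	33.2	8.9	1.2	43.4	Inner spiral sulcus
T9	0	1215	614	153	18	785	0.0	60.8	30.7	7.7	0.9	39.2	Kolliker organ
T10	3	1477	412	92	16	520	0.1	73.8	20.6	4.6	0.8	26.0	Stria vascularis
T11	5	1561	360	65	9	434	0.2	78.0	18.0	3.2	0.5	21.7	Outer spiral sulcus
T12	10	1116	661	187	26	874	0.5	55.8	33.0	9.3	1.3	43.7	Saccule sensory region
T13	8	1133	671	167	21	859	0.4	56.6	33.5	8.3	1.1	43.0	Saccule other cells
T14	10	1114	663	188	25	876	0.5	55.7	33.1	9.4	1.2	43.8	Utricule sensory region
T15	8	1131	671	166	24	861	0.4	56.5	33.5	8.3	1.2	43.0	Utricule other cells
T16	10	1110	662	192	26	880	0.5	55.5	33.1	9.6	1.3	44.0	Crista sensory region
T17	9	1132	670	164	25	859	0.5	56.6	33.5	8.2	1.2	43.0	Crista other cells
T18	11	1112	649	198	30	877	0.6	55.6	32.5	9.9	1.5	43.9	Semi-circular canals
T19	35	1386	470	97	12	579	1.8	69.3	23.5	4.8	0.6	28.9	Endolymphatic organ
T20	6	1022	651	264	57	972	0.3	51.1	32.5	13.2	2.9	48.6	Choroide plexus 4th ventricle
T21	0	455	793	570	182	1545	0.0	22.8	39.6	28.5	9.1	77.2	Hindbrain
T22	12	824	725	378	61	1164	0.6	41.2	36.2	18.9	3.0	58.2	Sensory retina
T23	6	818	830	299	47	1176	0.3	40.9	41.5	14.9	2.4	58.8	Olfactory organ
T24	11	1216	571	153	49	773	0.6	60.8	28.6	7.7	2.5	38.6	Cartilage primordium of ribs
T25	14	894	685	326	81	1092	0.7	44.7	34.2	16.3	4.0	54.6	Follicles of vibrissae
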