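feature_id	mz	rt	polarity	formula	class	ratio	ratio_sd	producer	intensity	high_signal	trajectory	p10_A	p20_A	p10_B	p20_B	sup_dependent	synthetic
F136.0403	136.0403	3.91	neg	C7H7NO2	newly_synthesized	NA	NA	B	80000	FALSE	increasing	0	0	0.13	0.19	TRUE	FALSE
F165.0554	165.0554	9.79	neg	C9H10O3	fold_increased	15.8	0.7	both	25000	FALSE	steady	0.17	0.17	0.15	0.15	TRUE	FALSE
F166.0507	166.0507	8.65	neg	C8H9NO3	newly_synthesized	NA	NA	none	80000	TRUE	na	0	0	0	0	NA	FALSE
F167.0348	167.0348	9.90	neg	C8H8O4	fold_increased	5.8	0.6	B	5000	FALSE	steady	0	0	0.14	0.14	TRUE	FALSE
F181.0615	181.0615	6.46	neg	C8H10N2O3	newly_synthesized	NA	NA	A	4000	FALSE	steady	0.18	0.18	0	0	TRUE	FALSE
F195.0505	195.0505	8.37	neg	C6H12O4	fold_increased	25.3	1.2	none	20000	TRUE	na	0	0	0	0	NA	FALSE
F244.0612	244.0612	6.86	neg	C13H11NO4	newly_synthesized	NA	NA	none	7000	FALSE	na	0	0	0	0	NA	FALSE
F249.1497	249.1497	16.33	neg	C15H22O3	newly_synthesized	NA	NA	A	15000	FALSE	steady	0.22	0.22	0	0	TRUE	FALSE
F251.0712	251.0712	15.72	neg	C16H12O3	fold_increased	7.3	1.3	A	6000	FALSE	steady	0.20	0.20	0	0	TRUE	FALSE
F269.0577	269.0577	11.75	neg	C14H10N2O4	newly_synthesized	NA	NA	B	9000	FALSE	steady	0	0	0.17	0.17	TRUE	FALSE
F271.0716	271.0716	7.03	neg	C14H12N2O4	newly_synthesized	NA	NA	B	100000	FALSE	steady	0	0	0.20	0.20	TRUE	FALSE
F271.0725	271.0725	10.25	neg	C14H12N2O4	newly_synthesized	NA	NA	B	110000	FALSE	steady	0	0	0.18	0.18	TRUE	FALSE
F279.0656	279.0656	13.25	neg	C17H12O4	fold_increased	5.2	1.3	A	250000	FALSE	increasing	0.16	0.22	0	0	TRUE	FALSE
F281.0808	281.0808	11.93	neg	C17H14O4	fold_increased	102.2	4.8	A	50000	FALSE	increasing	0.18	0.24	0	0	TRUE	FALSE
F298.0928	298.0928	8.65	neg	C13H17NO7	newly_synthesized	NA	NA	none	30000	TRUE	na	0	0	0	0	NA	FALSE
F304.0626	304.0626	3.33	neg	C9H13N3O9	newly_synthesized	NA	NA	none	25000	TRUE	na	0	0	0	0	NA	FALSE
F306.0775	306.0775	10.46	neg	C18H13NO4	newly_synthesized	NA	NA	none	30000	TRUE	na	0	0	0	0	NA	FALSE
F309.0756	309.0756	12.04	neg	C18H14O5	fold_increased	15.4	1.2	both	250000	FALSE	increasing	0.15	0.20	0.15	0.26	TRUE	FALSE
F311.0931	311.0931	11.49	neg	C18H16O5	fold_increased	400	7.1	A	40000	FALSE	increasing	0.15	0.21	0	0	TRUE	FALSE
F314.0899	314.0899	3.32	neg	C14H13N5O4	newly_synthesized	NA	NA	none	20000	TRUE	na	0	0	0	0	NA	FALSE
F330.2656	330.2656	14.03	neg	C18H37NO4	fold_increased	59.7	8.1	A	60000	FALSE	increasing	0.17	0.23	0	0	TRUE	FALSE
F334.0733	334.0733	11.44	neg	C20H9N5O4	newly_synthesized	NA	NA	none	40000	TRUE	na	0	0	0	0	NA	FALSE
F337.0712	337.0712	10.59	neg	C20H10N4O2	newly_synthesized	NA	NA	none	20000	TRUE	na	0	0	0	0	NA	FALSE
F341.1046	341.1046	16.16	neg	C20H14N4O2	newly_synthesized	NA	NA	A	5000	FALSE	steady	0.16	0.16	0	0	TRUE	FALSE
F342.2654	342.2654	15.17	neg	C19H37NO4	newly_synthesized	NA	NA	both	125000	FALSE	steady	0.19	0.19	0.16	0.16	TRUE	FALSE
F387.1926	387.1926	20.12	neg	C19H36N2S3	newly_synthesized	NA	NA	none	3000	FALSE	na	0	0	0	0	NA	FALSE
F389.2072	389.2072	20.07	neg	C19H38N2S3	newly_synthesized	NA	NA	none	3000	FALSE	na	0	0	0	0	NA	FALSE
F397.2230	397.2230	19.42	neg	C21H34O7	newly_synthesized	NA	NA	none	12500	TRUE	na	0	0	0	0	NA	FALSE
F398.1058	398.1058	13.53	neg	C25H13N5O	newly_synthesized	NA	NA	none	3000	FALSE	na	0	0	0	0	NA	FALSE
F399.2386	399.2386	20.07	neg	C21H36O7	fold_increased	103.3	4.2	none	3000	FALSE	na	0	0	0	0	NA	FALSE
F405.0737	405.0737	12.83	neg	C22H10N6O3	newly_synthesized	NA	NA	none	3000	FALSE	na	0	0	0	0	NA	FALSE
F406.1043	406.1043	7.89	neg	C22H13N7O2	newly_synthesized	NA	NA	none	3000	FALSE	na	0	0	0	0	NA	FALSE
F415.2338	415.2338	10.40	neg	C21H36O8	newly_synthesized	NA	NA	none	3000	FALSE	na	0	0	0	0	NA	FALSE
F436.2698	436.2698	15.86	neg	C24H39NO6	newly_synthesized	NA	NA	A	25000	FALSE	steady	0.19	0.19	0	0	TRUE	FALSE
F454.2817	454.2817	15.86	neg	C24H41NO7	newly_synthesized	NA	NA	A	15000	FALSE	steady	0.21	0.21	0	0	TRUE	FALSE
F455.1685	455.1685	8.64	neg	C21H24N6O6	newly_synthesized	NA	NA	none	3000	FALSE	na	0	0	0	0	NA	FALSE
F472.2923	472.2923	15.86	neg	C24H43NO8	newly_synthesized	NA	NA	A	12500	FALSE	steady	0.17	0.17	0	0	TRUE	FALSE
F490.3025	490.3025	15.06	neg	C24H45NO9	newly_synthesized	NA	NA	A	34000	FALSE	increasing	0.19	0.25	0	0	TRUE	FALSE
F567.3139	567.3139	15.87	neg	C25H48N2O12	newly_synthesized	NA	NA	A	7000	FALSE	steady	0.15	0.15	0	0	TRUE	FALSE
F581.1208	581.1208	13.24	neg	C36H22O8	newly_synthesized	NA	NA	none	3000	FALSE	na	0	0	0	0	NA	FALSE
F586.2857	586.2857	16.44	neg	C28H45NO12	newly_synthesized	NA	NA	none	2000	FALSE	na	0	0	0	0	NA	FALSE
F597.1968	597.1968	8.63	neg	C31H34O12	newly_synthesized	NA	NA	none	3000	FALSE	na	0	0	0	0	NA	FALSE
F629.1419	629.1419	11.77	neg	C30H22N4O12	newly_synthesized	NA	NA	none	3000	FALSE	na	0	0	0	0	NA	FALSE
F641.1461	641.1461	12.65	neg	C19H29N7O18	newly_synthesized	NA	NA	none	3000	FALSE	na	0	0	0	0	NA	FALSE
F140.0708	140.0708	8.64	pos	C7H9NO2	fold_increased	14.9	1.3	B	11000	FALSE	increasing	0	0	0.15	0.21	TRUE	FALSE
F150.0548	150.0548	8.53	pos	C8H7NO2	newly_synthesized	NA	NA	none	100000	TRUE	na	0	0	0	0	NA	FALSE
F160.0377	160.0377	3.84	pos	C4H5N3O4	newly_synthesized	NA	NA	none	3000	FALSE	na	0	0	0	0	NA	FALSE
F196.0944	196.0944	9.16	pos	C10H13NO3	newly_synthesized	NA	NA	none	2000	FALSE	na	0	0	0	0	NA	FALSE
F216.1021	216.1021	14.20	pos	C13H14NO2	newly_synthesized	NA	NA	none	10000	TRUE	na	0	0	0	0	NA	FALSE
F230.1177	230.1177	19.07	pos	C14H15NO2	newly_synthesized	NA	NA	none	2600	FALSE	na	0	0	0	0	NA	FALSE
F257.0919	257.0919	9.18	pos	C14H12N2O3	newly_synthesized	NA	NA	none	3000	FALSE	na	0	0	0	0	NA	FALSE
F265.0860	265.0860	11.92	pos	C17H12O3	fold_increased	802.4	9.6	none	20000	TRUE	na	0	0	0	0	NA	FALSE
F268.2277	268.2277	15.96	pos	C16H29NO2	newly_synthesized	NA	NA	none	4000	FALSE	na	0	0	0	0	NA	FALSE
F270.0979	270.0979	3.27	pos	C13H11N5O2	newly_synthesized	NA	NA	none	3000	FALSE	na	0	0	0	0	NA	FALSE
F272.1129	272.1129	3.58	pos	C12H17NO6	newly_synthesized	NA	NA	none	3000	FALSE	na	0	0	0	0	NA	FALSE
F286.1436	286.1436	14.85	pos	C17H19NO3	newly_synthesized	NA	NA	none	3000	FALSE	na	0	0	0	0	NA	FALSE
F287.1030	287.1030	10.61	pos	C16H10N6	newly_synthesized	NA	NA	none	3000	FALSE	na	0	0	0	0	NA	FALSE
F288.2900	288.2900	20.88	pos	C17H37NO2	fold_increased	50.5	3.3	A	19000	FALSE	increasing	0.14	0.20	0	0	TRUE	FALSE
F298.2744	298.2744	18.56	pos	C18H35NO2	newly_synthesized	NA	NA	A	40000	FALSE	steady	0.23	0.23	0	0	TRUE	FALSE
F302.3069	302.3069	21.38	pos	C18H39NO2	fold_increased	24.4	3.1	both	480000	FALSE	increasing	0.16	0.22	0.14	0.19	TRUE	FALSE
F322.0898	322.0898	8.70	pos	C11H11N7O5	newly_synthesized	NA	NA	none	3000	FALSE	na	0	0	0	0	NA	FALSE
F330.3371	330.3371	26.77	pos	C20H43NO2	fold_increased	152.3	1.6	A	5600	FALSE	steady	0.18	0.18	0	0	TRUE	FALSE
F334.2953	334.2953	14.95	pos	C18H39NO4	newly_synthesized	NA	NA	A	16000	FALSE	steady	0.20	0.20	0	0	TRUE	FALSE
F348.1430	348.1430	11.71	pos	C20H17N3O3	newly_synthesized	NA	NA	none	3000	FALSE	na	0	0	0	0	NA	FALSE
F358.2955	358.2955	15.66	pos	C20H39NO4	fold_increased	25.2	2.3	A	30000	FALSE	increasing	0.16	0.21	0	0	TRUE	FALSE
F369.2269	369.2269	13.47	pos	C16H28N6O4	newly_synthesized	NA	NA	none	3000	FALSE	na	0	0	0	0	NA	FALSE
F372.3113	372.3113	19.96	pos	C21H41NO4	newly_synthesized	NA	NA	both	360000	FALSE	steady	0.21	0.21	0.18	0.18	TRUE	FALSE
F377.2302	377.2302	20.09	pos	C18H28N6O3	newly_synthesized	NA	NA	none	3000	FALSE	na	0	0	0	0	NA	FALSE
F400.1019	400.1019	7.96	pos	C17H9N11O2	newly_synthesized	NA	NA	none	3000	FALSE	na	0	0	0	0	NA	FALSE
F432.1504	432.1504	8.68	pos	C19H21N5O7	newly_synthesized	NA	NA	none	3000	FALSE	na	0	0	0	0	NA	FALSE
F496.2886	496.2886	16.43	pos	C15H41N2O4	newly_synthesized	NA	NA	A	40000	FALSE	steady	0.16	0.16	0	0	TRUE	FALSE
F506.3332	506.3332	15.85	pos	C25H47NO9	newly_synthesized	NA	NA	A	30000	FALSE	steady	0.22	0.22	0	0	TRUE	FALSE
F716.5259	716.5259	18.91	pos	C42H69NO8	newly_synthesized	NA	NA	none	3000	FALSE	na	0	0	0	0	NA	FALSE
F453.2101	453.2101	17.50	pos	C22H30N2O8	newly_synthesized	NA	NA	none	5000	FALSE	na	0	0	0	0	NA	TRUE
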