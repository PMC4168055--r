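family	rpm_ct	rpm_hs	log2_hs_ct	p_value
miR156	945.57	1309.01	0.47	0.000000
miR159	51822.95	59294.59	0.19	0.000000
miR160	119.67	28.49	-2.07	0.000000
miR162	25.12	35.95	0.52	0.246230
miR164	118.20	114.62	-0.04	0.837848
miR166	645.64	1033.64	0.68	0.000000
miR167	234.91	220.43	-0.09	0.524589
miR168	1501.09	1526.72	0.02	0.664597
miR169	76.83	35.27	-1.12	0.000117
miR171	97.51	183.13	0.91	0.000002
miR172	-	13.56	-	0.000977
miR319	1886.70	3144.33	0.74	0.000000
miR3630	29.55	-	-	0.000000
miR390	32.50	25.09	-0.37	0.329586
miR393	59.10	25.09	-1.24	0.000196
miR394	17.73	19.67	0.15	0.867164
miR396	463.92	693.84	0.58	0.000000
miR397	-	21.03	-	0.000015
miR398	19.21	254.34	3.73	0.000000
miR408	91.60	853.91	3.22	0.000000
miR444	53.19	74.61	0.49	0.089931
miR528	132.97	214.32	0.69	0.000037
miR529	-	8.14	-	0.023690
miR827	-	13.56	-	0.000977
miR858	90.12	75.28	-0.26	0.285608
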