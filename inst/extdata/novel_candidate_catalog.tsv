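id	precursor_length	mfe	mfei	randfold_p	sequence	srna_length	rpm_ct	rpm_hs
Zma_miR_Seq01	169	-42.5	0.61	0.029703	AAAATTTAGAGGACGTTGCTGGAG	24	-	10.34
Zma_miR_Seq02	141	-84.8	1.15	0.009901	AAACCGTCGGAGATAGCTTATGTC	24	-	8.86
Zma_miR_Seq03	128	-76.7	1.08	0.009901	AACCTATGTCCGACGGTTTTAGGC	24	-	7.39
Zma_miR_Seq04	79	-26.4	0.52	0.09901	ACGTCTATGGTTAGATCACGCGGC	24	-	8.86
Zma_miR_Seq05	75	-23.9	0.70	0.049505	ATAACTGTAGTGCATTAAAGCGGG	24	4.07	7.39
Zma_miR_Seq06	173	-60.52	0.85	0.009901	ATCCATATGGACTGGGAGGAAAGC	24	-	44.32
Zma_miR_Seq07a	104	-58.3	0.80	0.009901	CCCGCCGGCGAGCGCTTTCCT	21	-	13.30
Zma_miR_Seq07b	104	-58.3	0.80	0.019802	CCCGCCGGCGAGCGCTTTCCT	21	-	13.30
Zma_miR_Seq08	170	-91.5	0.92	0.009901	CGGCGGGGGCGAACTGAGAAC	21	21.70	143.31
Zma_miR_Seq09a	161	-64.2	0.84	0.009901	CGTGGTATTGTTTCGGCTCATG	22	11.53	125.58
Zma_miR_Seq09b	123	-57.4	0.94	0.009901	CGTGGTATTGTTTCGGCTCATG	22	11.53	125.58
Zma_miR_Seq09c	123	-57.4	0.94	0.009901	CGTGGTATTGTTTCGGCTCATG	22	11.53	125.58
Zma_miR_Seq10	114	-31.3	0.68	0.059406	TCCTTGTTGGACAGATAAAGGAGC	24	-	7.39
Zma_miR_Seq11	85	-45.5	1.17	0.009901	TTGTTGGTCTATTCGGGTTTTCGA	24	-	7.39
Zma_miR_Seq12	143	-57.8	0.81	0.009901	CATGAACCGAGCGAGCTAGCGAGC	24	14.92	-
Zma_miR_Seq13	232	-110.7	0.75	0.009901	GGCGGACTGGGAACACATGGG	21	7.46	-
Zma_miR_Seq14	152	-103.3	1.45	0.009901	TTGGGAGCCACAAAACTGAAG	21	3.39	-
Zma_miR_Seq15	179	-84	1.00	0.009901	TTTTGTTGGTGGTCATTTAACC	22	14.24	-
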