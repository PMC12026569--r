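sample_id	ga_weeks	ga_days	ff_pct	result_type	acmg	genes
1	10	4	11	SNV	P	GJB2
2	11	5	7	WT	NA	NA
3	15	2	11	WT	NA	NA
4	14	0	10	DUP	VUS/P	NA
5	13	6	9	SNV	P	CFTR
6	12	0	8	DEL	P	NA
7	10	3	11	DEL	P	NA
8	12	6	14	WT	NA	NA
9	11	2	10	WT	NA	NA
10	12	5	5	DUP	P	NA
11	10	3	10	SNV	P	GJB2
12	13	5	9	SNV	P	RIT1
13	11	1	6	WT	NA	NA
14	12	0	6	SNV	P;P	PAH
15	11	0	14	WT	NA	NA
16	13	1	7	WT	NA	NA
17	12	5	17	SNV	VUS	DHCR7
18	12	2	14	WT	NA	NA
19	11	0	11	WT	NA	NA
20	12	0	5	WT	NA	NA
21	12	3	7	WT	NA	NA
22	12	4	7	SNV	P;P	GJB2
23	12	0	5	WT	NA	NA
24	9	0	10	WT	NA	NA
25	14	5	10	SNV	P	TCOF1
26	10	3	8	SNV	P	PTPN11
27	12	3	5	SNV	P	MCCC2
28	11	1	12	SNV	P	GJB2
29	13	3	20	SNV	P	GBA1
30	12	2	6	SNV	P	PTPN11
31	12	6	11	SNV	P/LP;P/LP	ABCA4;GBA1
32	11	3	12	SNV	P	PAH
33	10	4	9	SNV	LP	PAH
34	11	4	15	SNV	P	PTPN11
35	12	0	11	SNV	P	MYBPC3
36	12	0	18	SNV	P	GBA1
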