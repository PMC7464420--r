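chrom	snp_id	Angus	Charolais	Holstein	Limousin	overall	position_bp	interval_start	interval_end	genes
2	Hapmap49624-BTA-47893	0	0	0	15	15	6760630	6510630	7010630	PMS1, ORMDL1, OSGEPL1, ANKAR, ASNSD1, SLC40A1, LOC100848294, WDR75
4	Hapmap53144-ss46525999	0	0	15	0	15	76874783	76624783	77124783	MYO1G, LOC112446527, PURB, MIR4657, H2AFV, PPIA, ZMIZ2, LOC112446406, OGDH, TMED4, DDX56, NPC1L1, NUDCD3, LOC104972146, CAMK2B, YKT6
14	BTB-01532239	2	10	9	0	21	22781305	22531305	23031305	XKR4, TRNAT-AGU
14	BTB-01530788	3	9	10	9	31	22867321	22617321	23117321	XKR4, TRNAT-AGU, TMEM68, TGS1
14	BTB-00557532	6	10	9	11	36	22986080	22736080	23236080	XKR4, TRNAT-AGU, TMEM68, TGS1, LYN
14	Hapmap46986-BTA-34282	2	3	2	9	16	23630896	23380896	23880896	CHCHD7, SDR16C5, SDR16C6, PENK, LOC112449660, IMPAD1
14	Hapmap46735-BTA-86653	2	12	0	13	27	23725488	23475488	23975488	SDR16C6, PENK, LOC112449660, IMPAD1
14	ARS-BFGL-NGS-36089	1	5	0	10	16	24019648	23769648	24269648	LOC112449660, IMPAD1
14	Hapmap30932-BTC-011225	0	11	0	8	19	25082860	24832860	25332860	LOC107133116, TOX, TRNAC-GCA
14	BTB-01280026	4	9	0	4	17	25354206	25104206	25604206	TOX, TRNAC-GCA
14	Hapmap27934-BTC-065223	0	10	0	5	15	25472332	25222332	25722332	TOX
26	ARS-BFGL-NGS-11271	2	0	13	0	15	23039524	22789524	23289524	LDB1, PPRC1, LOC112444554, NOLC1, LOC112444524, LOC101902227, LOC785229, ELOVL3, PITX3, GBF1, NFKB2, PSD, FBXL15, CUEDC2, LOC112444535, MIR146B, MFSD13A, ACTR1A, SUFU, TRIM8
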