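# config_hash=5c206c0b
sample_id	biotype	n_transcripts	composition_pct	reads	read_count_pct
Exo1	protein_coding	149	60.3239	953	19.06
Exo1	retained_intron	29	11.7409	230	4.6
Exo1	lncRNA	28	11.336	1061	21.22
Exo1	nonsense_mediated_decay	14	5.66802	57	1.14
Exo1	processed_transcript	10	4.04858	42	0.84
Exo1	misc_RNA	9	3.64372	942	18.84
Exo1	rRNA	8	3.23887	1715	34.3
Exo1	other	0	0	0	0
Exo2	protein_coding	145	59.4262	922	18.44
Exo2	retained_intron	32	13.1148	215	4.3
Exo2	lncRNA	28	11.4754	1060	21.2
Exo2	nonsense_mediated_decay	13	5.32787	66	1.32
Exo2	processed_transcript	9	3.68852	41	0.82
Exo2	misc_RNA	9	3.68852	991	19.82
Exo2	rRNA	8	3.27869	1705	34.1
Exo2	other	0	0	0	0
Exo3	protein_coding	144	59.5041	945	18.9
Exo3	retained_intron	32	13.2231	173	3.46
Exo3	lncRNA	28	11.5702	1069	21.38
Exo3	nonsense_mediated_decay	14	5.78512	82	1.64
Exo3	processed_transcript	7	2.89256	37	0.74
Exo3	misc_RNA	9	3.71901	806	16.12
Exo3	rRNA	8	3.30579	1888	37.76
Exo3	other	0	0	0	0
MV1	protein_coding	136	58.8745	942	18.84
MV1	retained_intron	29	12.5541	271	5.42
MV1	lncRNA	30	12.987	1216	24.32
MV1	nonsense_mediated_decay	10	4.329	63	1.26
MV1	processed_transcript	7	3.0303	29	0.58
MV1	misc_RNA	11	4.7619	1330	26.6
MV1	rRNA	8	3.4632	1149	22.98
MV1	other	0	0	0	0
MV2	protein_coding	139	57.438	789	15.78
MV2	retained_intron	32	13.2231	194	3.88
MV2	lncRNA	30	12.3967	1094	21.88
MV2	nonsense_mediated_decay	13	5.3719	89	1.78
MV2	processed_transcript	9	3.71901	21	0.42
MV2	misc_RNA	11	4.54545	1173	23.46
MV2	rRNA	8	3.30579	1640	32.8
MV2	other	0	0	0	0
MV3	protein_coding	144	59.5041	957	19.14
MV3	retained_intron	29	11.9835	214	4.28
MV3	lncRNA	30	12.3967	1364	27.28
MV3	nonsense_mediated_decay	13	5.3719	95	1.9
MV3	processed_transcript	7	2.89256	34	0.68
MV3	misc_RNA	11	4.54545	1184	23.68
MV3	rRNA	8	3.30579	1152	23.04
MV3	other	0	0	0	0
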