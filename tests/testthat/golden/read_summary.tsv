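# config_hash=5c206c0b
sample_id	group	n_reads	mean_length	median_length	n50	max_length	mean_quality
Exo1	Exo	5000	420.407	355	593	2104	NA
Exo2	Exo	5000	415.995	345	593	2234	NA
Exo3	Exo	5000	434.843	359	593	2512	NA
MV1	MV	5000	380.261	308	527	2512	NA
MV2	MV	5000	381.772	308	536	2234	NA
MV3	MV	5000	380.7	302	537	2512	NA
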