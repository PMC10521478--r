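# config_hash=5c206c0b
sample_id	Exo1	Exo2	Exo3	MV1	MV2	MV3
Exo1	1	0.903815	0.895155	0.760584	0.775094	0.74425
Exo2	0.903815	1	0.89167	0.745681	0.767238	0.752253
Exo3	0.895155	0.89167	1	0.741464	0.774863	0.741561
MV1	0.760584	0.745681	0.741464	1	0.856805	0.851504
MV2	0.775094	0.767238	0.774863	0.856805	1	0.858958
MV3	0.74425	0.752253	0.741561	0.851504	0.858958	1
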