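# config_hash=5c206c0b
direction	bin	count
ambiguous_internal	[0.0,0.1)	0
ambiguous_internal	[0.1,0.2)	0
ambiguous_internal	[0.2,0.3)	0
ambiguous_internal	[0.3,0.4)	0
ambiguous_internal	[0.4,0.5)	0
ambiguous_internal	[0.5,0.6)	0
ambiguous_internal	[0.6,0.7)	0
ambiguous_internal	[0.7,0.8)	0
ambiguous_internal	[0.8,0.9)	0
deg_3to5	[0.0,0.1)	515
deg_3to5	[0.1,0.2)	1055
deg_3to5	[0.2,0.3)	1064
deg_3to5	[0.3,0.4)	1061
deg_3to5	[0.4,0.5)	1064
deg_3to5	[0.5,0.6)	1087
deg_3to5	[0.6,0.7)	1113
deg_3to5	[0.7,0.8)	1040
deg_3to5	[0.8,0.9)	919
deg_5to3	[0.0,0.1)	303
deg_5to3	[0.1,0.2)	523
deg_5to3	[0.2,0.3)	571
deg_5to3	[0.3,0.4)	588
deg_5to3	[0.4,0.5)	541
deg_5to3	[0.5,0.6)	567
deg_5to3	[0.6,0.7)	561
deg_5to3	[0.7,0.8)	562
deg_5to3	[0.8,0.9)	529
endo	[0.0,0.1)	435
endo	[0.1,0.2)	818
endo	[0.2,0.3)	863
endo	[0.3,0.4)	826
endo	[0.4,0.5)	895
endo	[0.5,0.6)	817
endo	[0.6,0.7)	839
endo	[0.7,0.8)	1589
endo	[0.8,0.9)	0
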