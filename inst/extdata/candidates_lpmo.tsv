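coding_region	accession	protein_id	sequence	domain	structure	interpro
FUN_000653-T1	CAI7987917.1	PutMoA	0	0	1	AA16 LPMO
FUN_000713-T1	CAI7987978.1	PutMoB	0	0	1	Rho factor associated
FUN_002573-T1	CAI7991617.1	PutMoC	0	1	0	-
FUN_002890-T1	CAI7992277.1	PutMoD	0	0	1	AA16 LPMO
FUN_002962-T1	CAI7992399.1	PutMoE	0	0	1	-
FUN_003190-T1	CAI7992922.1	PutMoF	0	0	1	Ferritin-like
FUN_003535-T1	CAI7993628.1	PutMoG	0	1	0	AA13 LPMO
FUN_003783-T1	CAI7994168.1	PutMoH	0	0	1	-
FUN_006366-T1	CAI7999797.1	PutMoI	1	1	1	AA9 LPMO
FUN_006413-T1	CAI7999893.1	PutMoJ	0	1	0	AA9 LPMO
FUN_006553-T1	CAI8000144.1	PutMoK	0	0	1	-
FUN_007242-T1	CAI8001774.1	PutMoL	0	1	0	AA9 LPMO
FUN_007666-T1	CAI8002525.1	PutMoM	1	1	1	AA9 LPMO
FUN_008106-T1	CAI8003467.1	PutMoN	1	1	0	AA9 LPMO
FUN_009239-T1	CAI7992001.1	PutMoO	0	0	1	-
FUN_010012-T1	CAI8003342.1	PutMoP	0	0	1	-
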