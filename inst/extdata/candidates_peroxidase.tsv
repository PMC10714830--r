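coding_region	accession	protein_id	sequence	domain	structure	interpro
FUN_002995-T1	CAI7992466.1	PutPoxA	0	0	1	DUF3632
FUN_003542-T1	CAI7993642.1	PutPoxB	0	0	1	Arabinofuranosidase
FUN_003618-T1	CAI7993895.1	PutPoxC	0	0	1	-
FUN_004484-T1	CAI7995643.1	PutPoxD	0	0	1	Cell division control
FUN_008413-T1	CAI8004205.1	PutPoxE	0	0	1	SIT4 phosphatase-associated
FUN_008923-T1	CAI7988420.1	PutPoxF	0	0	1	-
FUN_009329-T1	CAI7993214.1	PutPoxG	0	0	1	-
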