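coding_region	accession	protein_id	sequence	domain	structure	interpro
FUN_000263-T1	CAI7987524.1	PutLacA	0	1	0	-
FUN_000580-T1	CAI7987844.1	PutLacB	0	1	0	Phospodiesterase
FUN_000646-T1	CAI7987911.1	PutLacC	0	1	0	-
FUN_000759-T1	CAI7988026.1	PutLacD	1	1	0	Multi-copper oxidase
FUN_000832-T1	CAI7988099.1	PutLacE	0	1	0	-
FUN_001183-T1	CAI7988671.1	PutLacF	0	1	0	-
FUN_001583-T1	CAI7989479.1	PutLacG	0	1	0	Salt tolerance regulator
FUN_002249-T1	CAI7990863.1	PutLacH	1	1	1	AA1 multi-copper oxidase
FUN_002874-T1	CAI7992258.1	PutLacI	0	1	0	-
FUN_003732-T1	CAI7994085.1	PutLacJ	0	0	1	-
FUN_003828-T1	CAI7994234.1	PutLacK	0	1	0	-
FUN_004259-T1	CAI7995254.1	PutLacL	0	1	0	Nucleoside hydrolase
FUN_004616-T1	CAI7995870.1	PutLacM	0	1	0	-
FUN_004739-T1	CAI7996089.1	PutLacN	0	1	0	Fumarylacetoacetate hydrolase family
FUN_005132-T1	CAI7997298.1	PutLacO	0	1	1	AA1 multi-copper oxidase
FUN_005520-T1	CAI7998008.1	PutLacP	0	1	0	Diacylglycerol acyltransferase
FUN_006244-T1	CAI7999594.1	PutLacQ	0	1	0	-
FUN_006620-T1	CAI8000270.1	PutLacR	0	1	0	Fumarylacetoacetate hydrolase family
FUN_006720-T1	CAI8000684.1	PutLacS	0	1	0	Glycosyltransferase 90
FUN_007228-T1	CAI8001746.1	PutLacT	0	1	0	-
FUN_007508-T1	CAI8002246.1	PutLaU	0	1	0	Pex2
FUN_008329-T1	CAI8004041.1	PutLacV	0	1	0	ATPase-related
FUN_009491-T1	CAI7995256.1	PutLacW	0	1	0	Helicase
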