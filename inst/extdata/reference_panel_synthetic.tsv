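species	gene	lambda_max_nm	method	is_damselfish	site_46	site_49	site_52	site_86	site_90	site_91	site_93	site_97	site_109	site_113	site_114	site_116	site_118	site_265	site_125
Pomacentrus_amboinensis	SWS1	360	MSP	TRUE	F	F	T	F	S	V	P	S	A	E	A	L	A	W	S
Pomacentrus_coelestis	SWS1	358	MSP	TRUE	F	F	T	F	S	V	P	S	A	E	A	L	A	W	S
Dascyllus_trimaculatus	SWS1	368	MSP	TRUE	F	F	T	F	S	V	P	S	A	E	S	L	S	W	A
Oreochromis_niloticus	SWS1	360	in-vitro	FALSE	F	F	T	F	S	V	P	S	A	E	A	L	A	W	S
Metriaclima_zebra	SWS1	368	in-vitro	FALSE	F	F	T	F	S	V	P	S	A	E	S	L	S	W	S
Oryzias_latipes	SWS1	356	in-vitro	FALSE	F	F	T	F	S	V	P	S	A	E	A	L	A	W	S
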