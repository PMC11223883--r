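motif_id	name	pattern	location_class	pathway	source
NT_ARGN_T1	Arg/N-degron type-1 primary residue	[RKH]	N_TERMINAL	Arg/N	Bachmair et al. 1986; Varshavsky 2019
NT_ARGN_T2	Arg/N-degron type-2 primary residue	[FWYLI]	N_TERMINAL	Arg/N	Bachmair et al. 1986; Varshavsky 2019
NT_ARGN_SEC	Arg/N-degron secondary residue	[DE]	N_TERMINAL	Arg/N	Varshavsky 2019
NT_ARGN_TER	Arg/N-degron tertiary residue	[NQC]	N_TERMINAL	Arg/N	Varshavsky 2019
CT_GG	C-terminal diglycine degron	GG	C_TERMINAL	C-degron:-GG	Koren et al. 2018; Timms & Koren 2020
CT_RG	C-terminal -RG degron	RG	C_TERMINAL	C-degron:-RG	Koren et al. 2018
CT_RXXG	C-terminal -RxxG degron	RxxG	C_TERMINAL	C-degron:-RxxG	Koren et al. 2018
CT_EE	C-terminal -EE degron	EE	C_TERMINAL	C-degron:-EE	Koren et al. 2018
CT_VX	C-terminal -VX degron	Vx	C_TERMINAL	C-degron:-VX	Koren et al. 2018
CT_A	C-terminal -A degron	A	C_TERMINAL	C-degron:-A	Koren et al. 2018; Lin et al. 2018
INT_DBOX	APC/C destruction box	RxxLxx[LIVM]x[ND]	INTERNAL	APC/C D-box	Glotzer et al. 1991; He et al. 2017
INT_KEN	APC/C KEN-box	KEN	INTERNAL	APC/C KEN-box	Pfleger & Kirschner 2000
INT_TRCP	SCF/beta-TrCP phosphodegron	DSGxxS	INTERNAL	SCF beta-TrCP	Frescas & Pagano 2008
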