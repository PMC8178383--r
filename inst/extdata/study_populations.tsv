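cross	pop_type	pop_size	trait	n_qtl
Langdon x G18-16	RIL	156	CIR	6
Langdon x G18-16	RIL	156	OP	9
Langdon x G18-16	RIL	156	CC	7
Langdon x G18-16	RIL	156	FLRI	9
Kofa x Svevo	RIL	247	PDL	4
Kofa x Svevo	RIL	247	SPAD	3
Kofa x Svevo	RIL	247	NDVI	5
Omrabi5 x Belikh2	RIL	114	CL	5
Omrabi5 x Belikh2	RIL	114	RRT	1
Colosseo x Lloyd	RIL	176	RRT	28
Meridiano x Claudio	RIL	181	RRT	32
Simeto x Mollise Colli	RIL	136	RRT	18
Strongfield x Blackbird	DH	85	FHB	2
LDN x LDN-Dic7A	RIL	118	FHB	1
Colosseo x Lloyd	RIL	176	LR	1
Meridiano x Claudio	RIL	181	SBCMV	1
DS x Td161	BC	134	FHB	1
Floradur x Td161	BC	129	FHB	3
Helidur x Td161	BC	126	FHB	1
Kristal x Sebatel	RIL	85	SR	7
Simeto x Levante	RIL	180	SBCMV	7
BGRC3487 x 2*DT735	RIL	160	FHB	2
Cirillo x Neodur	RIL	146	SBCMV	2
Wollaroi x Bansi	RIL	92	YR	2
Gerizim x Helidur	RIL	103	FHB	1
Langdon x G18-16	RIL	157	PM	4
Latino x MG5323	RIL	110	LR	3
Ben x PI41025	RIL	200	FHB	3
Sumai-3 x Saragolla	RIL	135	FHB	11
Karur x DBC-480	RIL	111	FHB	1
Strongfield x Blackbird	DH	90	LS	2
Kofa x W9262-260D3	DH	155	YR	1
Joppa x 10Ae564	RIL	205	FHB	3
Rusty x PI 192051-1	RIL	180	LR	5
Ben x Tunisian 108	BIL	171	FHB	3
Greenshank x AC Avonlea	DH	132	CP	4
UC1113 x Kofa	BP	93	YPC	4
Langdon x G18-16	RIL	152	GCaC	5
Langdon x G18-16	RIL	152	GCuC	10
Langdon x G18-16	RIL	152	GFeC	10
Langdon x G18-16	RIL	152	GKC	8
Langdon x G18-16	RIL	152	GMgC	2
Langdon x G18-16	RIL	152	GMnC	2
Langdon x G18-16	RIL	152	GPC	4
Langdon x G18-16	RIL	152	GSC	5
Langdon x G18-16	RIL	152	GZnC	6
Langdon x G18-16	RIL	152	PGC	3
DT695 x Strongfield	DH	185	GPC	6
Latino x Primadur	BP	121	YPC	4
UC1113 x Kofa	RIL	93	GPC	8
UC1113 x Kofa	RIL	93	SV	10
UC1113 x Kofa	BP	93	Fb	7
UC1113 x Kofa	BP	93	YPC	6
Svevo x Ciccio	BP	120	YPC	7
Duilio x Avonlea	RIL	134	BG	2
Langdon x G18-16	RIL	152	GSeC	9
Langdon x G18-16	RIL	152	GSeY	6
Colosseo x Lloyd	BP	176	YPC	9
Kofa x Svevo	BP	249	YPC	9
Meridiano x Claudio	BP	181	YPC	6
Svevo x Y12-3	RIL	208	GPC	12
Saragolla x 02-5B-318	RIL	135	GPC	4
Pelissier x Strongfield	DH	162	SV	6
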