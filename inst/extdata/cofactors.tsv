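resource	identifier	name
chebi	CHEBI:15422	ATP
chebi	CHEBI:16761	ADP
chebi	CHEBI:16027	AMP
chebi	CHEBI:15846	NAD(+)
chebi	CHEBI:16908	NADH
chebi	CHEBI:18009	NADP(+)
chebi	CHEBI:16474	NADPH
chebi	CHEBI:15377	water
chebi	CHEBI:15378	proton
chebi	CHEBI:18367	phosphate
chebi	CHEBI:16526	CO2
chebi	CHEBI:15379	O2
kegg.compound	C00002	ATP
kegg.compound	C00008	ADP
kegg.compound	C00020	AMP
kegg.compound	C00003	NAD+
kegg.compound	C00004	NADH
kegg.compound	C00006	NADP+
kegg.compound	C00005	NADPH
kegg.compound	C00001	H2O
kegg.compound	C00080	H+
kegg.compound	C00009	Orthophosphate
kegg.compound	C00011	CO2
kegg.compound	C00007	O2
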