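# PTM reaction catalogue.
#
# One row per (reaction_id, target) pair.  The catalogue has two layers:
# rows with a template_id are executable (a geometric template is packaged);
# rows with template_id "-" are names-layer entries recording reaction and
# product identity only.  Several reactions share a product code: distinct
# reactions may yield the same final modification (e.g. enzymatic
# carbonylation and metal-catalyzed oxidation of lysine both give the
# 2-aminoadipate semialdehyde product).
#
# Product codes marked wwpdb are chemical-component-dictionary codes;
# "local" codes are package-local 3-letter inventions for products without
# a (known) wwPDB code.
#
# NOTE: the source server's full catalogue (256 reactions / 110 products)
# is defined in supplementary material that is not packaged here; this
# table is a documented representative subset.
#
# reaction_id	target	product_code	template_id	code_origin	description
phosphorylation	SER	SEP	phos_ser	wwpdb	O-phosphorylation of serine hydroxyl
phosphorylation	THR	TPO	phos_thr	wwpdb	O-phosphorylation of threonine hydroxyl
phosphorylation	TYR	PTR	phos_tyr	wwpdb	O-phosphorylation of tyrosine hydroxyl
phosphorylation	HIS	NEP	-	wwpdb	N-phosphorylation of histidine ring nitrogen
phosphorylation	ASP	DPO	-	local	aspartyl phosphate
phosphorylation	LYS	KPO	-	local	N-epsilon-phospholysine
phosphorylation	ARG	RPO	-	local	omega-N-phosphoarginine
acetylation	LYS	ALY	acet_lys	wwpdb	N-epsilon-acetylation of lysine
acetylation	SER	SAC	-	local	O-acetylserine
acetylation	THR	TAC	-	local	O-acetylthreonine
acetylation	NTER:ALA	AYA	nterm_acet_ala	wwpdb	N-terminal acetylation (alanine)
acetylation	NTER:GLY	GAC	-	local	N-terminal acetylation (glycine)
acetylation	NTER:SER	SAN	-	local	N-terminal acetylation (serine)
acetylation	NTER:MET	MAN	-	local	N-terminal acetylation (methionine)
methylation	LYS	MLZ	meth_lys_mono	wwpdb	N-epsilon-monomethylation of lysine
methylation	MLZ	MLY	meth_mlz_di	wwpdb	second methylation of monomethyllysine
methylation	MLY	M3L	meth_mly_tri	wwpdb	third methylation of dimethyllysine
methylation	ARG	RME	meth_arg	local	omega-N-monomethylation of arginine
methylation	GLU	EME	-	local	glutamate carboxymethylation
methylation	HIS	HME	-	local	histidine ring methylation
methylation	GLN	QME	-	local	glutamine N5-methylation
dimethylation	LYS	MLY	meth_lys_di	wwpdb	N-epsilon-dimethylation of lysine
dimethylation-asymmetric	ARG	RMA	-	local	asymmetric omega-N,N-dimethylarginine
dimethylation-symmetric	ARG	RMS	-	local	symmetric omega-N,N'-dimethylarginine
trimethylation	LYS	M3L	meth_lys_tri	wwpdb	N-epsilon-trimethylation of lysine
hydroxylation	PRO	HYP	hydroxy_pro	wwpdb	4-hydroxylation of proline
hydroxylation	LYS	LYZ	-	wwpdb	5-hydroxylation of lysine
hydroxylation	ASN	NHY	-	local	beta-hydroxyasparagine
hydroxylation	ASP	DHY	-	local	beta-hydroxyaspartate
hydroxylation	PHE	FHY	-	local	meta-hydroxyphenylalanine
carboxylation	GLU	CGU	carboxy_glu	wwpdb	gamma-carboxylation of glutamate
carboxylation	ASP	DCX	-	local	beta-carboxylation of aspartate
nitration	TYR	NIY	nitro_tyr	wwpdb	3-nitration of tyrosine
nitration	TRP	WNO	-	local	6-nitrotryptophan
carbonylation	LYS	KCA	carbonyl_lys	local	lysine to 2-aminoadipate semialdehyde (allysine)
carbonylation	ARG	RCA	carbonyl_arg	local	arginine to glutamate semialdehyde
carbonylation	PRO	PCB	carbonyl_pro	local	proline ring carbonylation
carbonylation	THR	TCA	carbonyl_thr	local	threonine to 2-amino-3-oxobutyrate
metal-catalyzed-oxidation	LYS	KCA	-	local	oxidative carbonylation of lysine
metal-catalyzed-oxidation	ARG	RCA	-	local	oxidative carbonylation of arginine
metal-catalyzed-oxidation	PRO	PCB	-	local	oxidative carbonylation of proline
metal-catalyzed-oxidation	THR	TCA	-	local	oxidative carbonylation of threonine
deamidation	ASN	ASP	deamid_asn	wwpdb	deamidation of asparagine to aspartate
deamidation	GLN	GLU	deamid_gln	wwpdb	deamidation of glutamine to glutamate
amidation	ASP	ASN	amid_asp	wwpdb	amidation of aspartate to asparagine
amidation	GLU	GLN	amid_glu	wwpdb	amidation of glutamate to glutamine
oxidation	MET	MOX	oxid_met	local	methionine sulfoxide
oxidation	CYS	CSO	oxid_cys	wwpdb	cysteine sulfenic acid (S-hydroxycysteine)
oxidation	TRP	WOX	-	local	tryptophan 2-oxidation
oxidation	HIS	HOX	-	local	2-oxohistidine
dioxidation	MET	MO2	-	local	methionine sulfone
dioxidation	CYS	CSD	-	wwpdb	cysteine sulfinic acid
citrullination	ARG	CIR	-	wwpdb	deimination of arginine to citrulline
sulfation	TYR	TYS	-	wwpdb	O-sulfation of tyrosine
nitrosylation	CYS	SNC	-	wwpdb	S-nitrosocysteine
glutathionylation	CYS	GSC	-	local	S-glutathionylation of cysteine
palmitoylation	CYS	PMC	-	local	S-palmitoylation of cysteine
prenylation	CYS	FRC	-	local	S-farnesylation of cysteine
formylation	LYS	KFO	-	local	N-epsilon-formylation of lysine
succinylation	LYS	KSU	-	local	N-epsilon-succinylation of lysine
malonylation	LYS	KMA	-	local	N-epsilon-malonylation of lysine
crotonylation	LYS	KCR	-	local	N-epsilon-crotonylation of lysine
myristoylation	NTER:GLY	GMY	-	local	N-terminal myristoylation (glycine)
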