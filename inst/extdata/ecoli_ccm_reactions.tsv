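reaction_id	enzyme_id	substrates	products	reversible
R_glk	glk	glc;atp	g6p;adp	FALSE
R_pgi	pgi	g6p	f6p	TRUE
R_pfkA	pfkA	f6p;atp	fbp;adp	FALSE
R_fbp	fbp	fbp;h2o	f6p;pi	FALSE
R_fbaA	fbaA	fbp	dhap;g3p	TRUE
R_tpiA	tpiA	dhap	g3p	TRUE
R_gapA	gapA	g3p;nad;pi	bpg13;nadh	TRUE
R_pgk	pgk	bpg13;adp	pg3;atp	TRUE
R_gpmA	gpmA	pg3	pg2	TRUE
R_eno	eno	pg2	pep;h2o	TRUE
R_pykF	pykF	pep;adp	pyr;atp	FALSE
R_pykA	pykA	pep;adp	pyr;atp	FALSE
R_ppsA	ppsA	pyr;atp;h2o	pep;amp;pi	FALSE
R_aceE	aceE	pyr;coa;nad	accoa;co2;nadh	FALSE
R_pta	pta	accoa;pi	actp;coa	TRUE
R_ackA	ackA	actp;adp	ac;atp	TRUE
R_acs	acs	ac;atp;coa	accoa;amp;ppi	FALSE
R_zwf	zwf	g6p;nadp	pgl;nadph	FALSE
R_pgl	pgl	pgl;h2o	pgc	FALSE
R_gnd	gnd	pgc;nadp	ru5p;co2;nadph	FALSE
R_rpiA	rpiA	ru5p	r5p	TRUE
R_rpe	rpe	ru5p	x5p	TRUE
R_tktA	tktA	x5p;r5p	s7p;g3p	TRUE
R_talB	talB	s7p;g3p	e4p;f6p	TRUE
R_tktB	tktB	x5p;e4p	f6p;g3p	TRUE
R_prs	prs	r5p;atp	prpp;amp	FALSE
R_gltA	gltA	accoa;oaa;h2o	cit;coa	FALSE
R_acnB1	acnB	cit	acon;h2o	TRUE
R_acnB2	acnB	acon;h2o	icit	TRUE
R_icd	icd	icit;nadp	akg;co2;nadph	FALSE
R_sucAB	sucB	akg;coa;nad	succoa;co2;nadh	FALSE
R_sucCD	sucC	succoa;adp;pi	succ;atp;coa	TRUE
R_sdhA	sdhA	succ	fum	TRUE
R_fumA	fumA	fum;h2o	mal	TRUE
R_mdh	mdh	mal;nad	oaa;nadh	TRUE
R_aceA	aceA	icit	succ;glx	FALSE
R_aceB	aceB	glx;accoa;h2o	mal;coa	FALSE
R_ppc	ppc	pep;co2;h2o	oaa;pi	FALSE
R_pck	pck	oaa;atp	pep;co2;adp	FALSE
R_maeB	maeB	mal;nadp	pyr;co2;nadph	FALSE
R_glpK	glpK	glyc;atp	glyc3p;adp	FALSE
R_glpD	glpD	glyc3p;nad	dhap;nadh	FALSE
R_manX	manX	fru;pep	f6p;pyr	FALSE
R_mgsA	mgsA	dhap	mgx;pi	FALSE
R_gloA	gloA	mgx;gsh	lgt	FALSE
R_gloB	gloB	lgt;h2o	lac;gsh	FALSE
R_ldhA	ldhA	pyr;nadh	lac;nad	TRUE
R_gdhA	gdhA	akg;nadph;nh4	glu;nadp	TRUE
R_glnA	glnA	glu;atp;nh4	gln;adp;pi	FALSE
R_aspC	aspC	oaa;glu	asp;akg	TRUE
R_alaC	alaC	pyr;glu	ala;akg	TRUE
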