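ko_id	locus	gene_name	reg_type	function	is_sporulation
K01356	BSU_17850	lexA	R	lexA repressor	TRUE
K03086	BSU_25200	sigA	R	RNA polymerase sigma factor RpoD	TRUE
K03091	BSU_00980	sigH	R	RNA polymerase sigma-H factor	TRUE
K03091	BSU_15320	sigE	R	RNA polymerase sigma-E factor	TRUE
K03091	BSU_15330	sigG	R	RNA polymerase sigma-G factor	TRUE
K03091	BSU_23450	sigF	R	RNA polymerase sigma-F factor	TRUE
K03091	CD630_07720	sigF	R	RNA polymerase sigma-F factor	TRUE
K03091	CD630_12300	sigK	R	RNA polymerase sigma-K factor	TRUE
K03091	CD630_26420	sigG	R	RNA polymerase sigma-G factor	TRUE
K03091	CD630_26430	sigE	R	RNA polymerase sigma-E factor	TRUE
K04769	BSU_560	spoVT	R	Stage V sporulation protein T	TRUE
K04769	CD630_34990	spoVT	R	Stage V sporulation protein T	TRUE
K06283	BSU_36420	spoIIID	R	Stage III sporulation protein D	TRUE
K06283	CD630_1260	spoIIID	R	Stage III sporulation protein D	TRUE
K06284	BSU_370	abrB	R	Transition state regulatory protein AbrB	TRUE
K07699	BSU_24220	spo0A	R	Stage 0 sporulation protein A	TRUE
K07699	CD630_12140	spo0A	R	Stage 0 sporulation protein A	TRUE
K07738	CD630_26400	nrdR	R	Transcriptional regulator, repressor NrdR family	TRUE
K03496	BSU_40970	parA	R+NR	Sporulation initiation inhibitor protein Soj	TRUE
K03496	CD630_36720	soj	R+NR	Transcriptional regulator, sporulation initiation inhibitor, chromosome partitioning protein	TRUE
K00390	BSU_10930	yitB	NR	Phosphoadenosine phosphosulfate reductase	TRUE
K00640	CD630_15950	cysE	NR	Serine acetyltransferase (SAT)	TRUE
K00820	CD630_1200	glmS	NR	Glucosamine-fructose-6-phosphate aminotransferase (isomerizing)	TRUE
K00974	BSU_22450	cca	NR	CCA-adding enzyme	TRUE
K01142	BSU_40880	exoA	NR	Exodeoxyribonuclease, repair of oxidative DNA damage in spores	TRUE
K01449	BSU_02600	cwlJ	NR	Cell wall hydrolase CwlJ	TRUE
K01449	BSU_22930	sleB	NR	Spore cortex-lytic enzyme	TRUE
K01449	CD630_35630	NA	NR	Putative spore cortex-lytic hydrolase	TRUE
K02049	BSU_30610	ytlC	NR	ABC transporter ATP-binding protein	TRUE
K02343	CD630_160	dnaX	NR	DNA polymerase III subunits gamma and tau	TRUE
K03466	BSU_16800	spoIIIE	NR	Spore DNA translocase	TRUE
K03497	BSU_40960	parB	NR	Stage 0 sporulation protein J	TRUE
K03497	CD630_36710	spo0J	NR	Stage 0 sporulation protein J, site-specific DNA-binding protein	TRUE
K03657	CD630_7490	NA	NR	Putative DNA helicase, UvrD/REP type	TRUE
K03664	BSU_33600	smpB	NR	SsrA-binding protein	TRUE
K03698	BSU_9930	yhaM	NR	3'-5' exoribonuclease yhaM	TRUE
K06381	BSU_36750	spoIID	NR	Stage II sporulation protein D	TRUE
K06381	CD630_1240	spoIID	NR	Stage II sporulation protein D	TRUE
K06412	BSU_490	spoVG	NR	Septation protein SpoVG	TRUE
K06412	CD630_35160	spoVG	NR	Regulator required for spore cortex synthesis	TRUE
K07171	CD630_34610	endoA	NR	Endoribonuclease toxin	TRUE
K10716	BSU_31322	yugO	NR	Potassium channel protein YugO	TRUE
K10979	BSU_13410	ykoV	NR	DNA repair protein YkoV	TRUE
K014487	BSU_17410	cwlC	NR	Mother cell lysis	TRUE
K014487	BSU_01530	cwlD	NR	Spore cortex peptidoglycan synthesis	TRUE
K02647	BSU_28670	ysfB	U	Hypothetical protein; similar to carbohydrate diacid transcriptional activator	TRUE
K03469	BSU_21970	ypeP	U	Hypothetical protein; similar to RNase HI	TRUE
K07175	BSU_14810	ylaK	U	Hypothetical protein; similar to PhoH	TRUE
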