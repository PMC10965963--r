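# Mapping of core-model reactions to iJN1463 reaction ids (BIGG namespace).
# sign = -1 where the GEM direction convention opposes the core model
# (e.g. RPI is written R5P -> Ru5P, TPI as DHAP consumer, FBA glycolytic).
# Grouped entries (semicolon-separated) are constrained on their summed flux,
# as done for the two malate dehydrogenase reactions MDH and MDH2.
core_rxn	gem_ids	sign
pgi	PGI	1
zwf	G6PDH2r	1
gnd	GND	1
edd	EDD	1
eda	EDA	1
tkt1	TKT1	1
tkt2	TKT2	1
tal	TALA	1
rpe	RPE	-1
rpi	RPI	-1
fba	FBA	-1
fbp	FBP	1
tpi	TPI	-1
gap	GAPD	1
pyk	PYK	1
ppc	PPC	1
pdh	PDH	1
mae	ME1;ME2	1
glt	CS	1
acn	ACONTa	1
icd	ICDHyr	1
akgd	AKGDH	1
icl	ICL	1
glcb	MALS	1
sdh	SUCDi	1
fum	FUM	1
mdh	MDH;MDH2	1
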