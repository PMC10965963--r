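# Synthetic reconstruction of the xylose-grown EDEMP-cycle flux map:
# steady-state-exact flux distribution consistent with the reported
# aggregate flux statements (Pgi = 89% of uptake; >50% of the 6PG node
# through Edd; >1/3 of the 6PG node recycled through Gnd) and with
# growth 0.08 h^-1 at the measured uptake rate.  Not measured data;
# SDs are plausible invented values.  Units: molar % of xylose uptake.
# uptake_rate_abs = 1.45
reaction	net_pct	sd_pct	exch_pct
upt	100.000000	0	0
xylA	100.000000	3	0
xylB	100.000000	3	0
rpe	-10.823908	0.4	0
rpi	45.823908	1.37	0
tkt1	45.327356	1.36	10
tkt2	43.848736	1.32	10
tal	45.327356	1.36	10
pgi	89.000000	2.67	10
zwf	87.868966	2.64	0
gnd	35.000000	1.05	0
edd	52.868966	1.59	0
eda	52.868966	1.59	0
fba	0.215632	0.4	0
fbp	0.215632	0.4	0
tpi	0.215632	0.4	0
gap	95.574713	2.87	0
pyk	73.898851	2.22	0
ppc	18.812414	0.56	0
pyc	-0.000000	0.4	0
pdh	116.137471	3.48	0
mae	5.000000	0.4	0
glt	97.977471	2.94	0
acn	97.977471	2.94	0
icd	95.977471	2.88	0
akgd	90.024368	2.7	0
icl	2.000000	0.4	0
glcb	2.000000	0.4	0
sdh	92.024368	2.76	0
fum	92.024368	2.76	0
mdh	89.024368	2.67	0
bm	5.517241	0.4	0
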