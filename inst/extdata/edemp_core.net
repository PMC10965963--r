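# Atom-mapped core network: xylose isomerase pathway feeding the EDEMP cycle
# (non-oxidative PPP + ED + gluconeogenic EMP steps) and the TCA cycle with
# glyoxylate shunt, for engineered P. putida growing on D-xylose.
# Atom maps follow the canonical central-carbon transition conventions of the
# 13C-MFA literature; symmetric succinate/fumarate handling is modelled as
# 50/50 orientation alternatives.  Zwf+Pgl are lumped, as are the lower
# glycolytic steps Gap..Eno (one G3P -> PEP step).
@substrate XYL_ext
@uptake upt
@unbalanced XYL_ext CO2

upt: XYL_ext (abcde) -> XYL (abcde) | Uptake
xylA: XYL (abcde) -> XLU (abcde) | XylA
xylB: XLU (abcde) -> X5P (abcde) | XylB
rpe: Ru5P (abcde) <-> X5P (abcde) | Rpe
rpi: Ru5P (abcde) <-> R5P (abcde) | RpiA
tkt1: X5P (abcde) + R5P (fghij) <-> S7P (abfghij) + G3P (cde) | Tkt
tkt2: X5P (abcde) + E4P (fghi) <-> F6P (abfghi) + G3P (cde) | Tkt
tal: S7P (abcdefg) + G3P (hij) <-> F6P (abchij) + E4P (defg) | Tal
pgi: F6P (abcdef) <-> G6P (abcdef) | Pgi
zwf: G6P (abcdef) -> 6PG (abcdef) | Zwf/Pgl
gnd: 6PG (abcdef) -> Ru5P (bcdef) + CO2 (a) | Gnd
edd: 6PG (abcdef) -> KDPG (abcdef) | Edd
eda: KDPG (abcdef) -> PYR (abc) + G3P (def) | Eda
fba: DHAP (cba) + G3P (def) <-> FBP (abcdef) | Fba
fbp: FBP (abcdef) -> F6P (abcdef) | Fbp
tpi: G3P (abc) <-> DHAP (cba) | TpiA
gap: G3P (abc) -> PEP (abc) | Gap/Pgk/Pgm/Eno
pyk: PEP (abc) -> PYR (abc) | Pyk
ppc: PEP (abc) + CO2 (d) -> OAA (abcd) | Ppc
pyc: PYR (abc) + CO2 (d) -> OAA (abcd) | Pyc
pdh: PYR (abc) -> AcCoA (bc) + CO2 (a) | Pdh
mae: MAL (abcd) -> PYR (abc) + CO2 (d) | MaeB
glt: OAA (abcd) + AcCoA (ef) -> CIT (dcbfea) | GltA
acn: CIT (abcdef) -> ICIT (abcdef) | Acn
icd: ICIT (abcdef) -> AKG (abcde) + CO2 (f) | Icd
akgd: AKG (abcde) -> 0.5 SUC (bcde) + 0.5 SUC (edcb) + CO2 (a) | 2Kgd
icl: ICIT (abcdef) -> GLX (ab) + 0.5 SUC (cdef) + 0.5 SUC (fedc) | AceA
glcb: GLX (ab) + AcCoA (cd) -> MAL (abdc) | GlcB
sdh: SUC (abcd) -> 0.5 FUM (abcd) + 0.5 FUM (dcba) | Sdh
fum: FUM (abcd) <-> 0.5 MAL (abcd) + 0.5 MAL (dcba) | FumC
mdh: MAL (abcd) <-> OAA (abcd) | Mdh
# Lumped biomass drain: precursor demands in mmol per gCDW; flux in units of
# (% uptake) * (gCDW/mmol xylose), i.e. 100*mu/q_S.
bm: 0.205 G6P + 0.071 F6P + 0.090 R5P + 0.268 E4P + 0.129 G3P + 0.519 PEP + 2.833 PYR + 2.929 AcCoA + 1.787 OAA + 1.079 AKG -> | Biomass
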