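# Elemental composition of the observed (derivatized) fragments.
# TBDMS amino-acid fragments: standard [M-57]/[M-159] compositions of the
# di/tri-TBDMS derivatives; sugar phosphates observed underivatized (IC-MS).
# backbone_carbons = carbon positions belonging to the metabolite backbone
# (the correctable label positions); remaining atoms contribute only natural
# isotope abundance.
fragment_id,C,H,N,O,Si,S,backbone_carbons
Ala[1-3],11,26,1,2,2,0,3
Ala[2-3],10,26,1,1,2,0,2
Gly[1-2],10,24,1,2,2,0,2
Ser[1-3],17,40,1,3,3,0,3
Asp[1-4],18,40,1,4,3,0,4
Asp[2-4],17,40,1,3,3,0,3
Glu[1-5],19,42,1,4,3,0,5
Glu[2-5],18,42,1,3,3,0,4
X5P[1-5],5,11,0,8,0,0,5
R5P[1-5],5,11,0,8,0,0,5
S7P[1-7],7,15,0,10,0,0,7
F6P[1-6],6,13,0,9,0,0,6
G6P[1-6],6,13,0,9,0,0,6
6PG[1-6],6,13,0,10,0,0,6
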