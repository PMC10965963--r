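{
  "comment": "Measurement set for the xylose EDEMP core model: GC-MS TBDMS amino-acid fragments mapped to their biosynthetic precursor metabolites, plus intact intracellular sugar-phosphate MIDs (IC-MS).",
  "fragments": [
    {"fragment_id": "Ala[1-3]", "metabolite": "PYR",  "carbons": "1-3", "instrument": "gcms_tbdms"},
    {"fragment_id": "Ala[2-3]", "metabolite": "PYR",  "carbons": "2-3", "instrument": "gcms_tbdms"},
    {"fragment_id": "Gly[1-2]", "metabolite": "G3P",  "carbons": "1-2", "instrument": "gcms_tbdms"},
    {"fragment_id": "Ser[1-3]", "metabolite": "G3P",  "carbons": "1-3", "instrument": "gcms_tbdms"},
    {"fragment_id": "Asp[1-4]", "metabolite": "OAA",  "carbons": "1-4", "instrument": "gcms_tbdms"},
    {"fragment_id": "Asp[2-4]", "metabolite": "OAA",  "carbons": "2-4", "instrument": "gcms_tbdms"},
    {"fragment_id": "Glu[1-5]", "metabolite": "AKG",  "carbons": "1-5", "instrument": "gcms_tbdms"},
    {"fragment_id": "Glu[2-5]", "metabolite": "AKG",  "carbons": "2-5", "instrument": "gcms_tbdms"},
    {"fragment_id": "X5P[1-5]", "metabolite": "X5P",  "carbons": "1-5", "instrument": "icms_sugarP"},
    {"fragment_id": "R5P[1-5]", "metabolite": "R5P",  "carbons": "1-5", "instrument": "icms_sugarP"},
    {"fragment_id": "S7P[1-7]", "metabolite": "S7P",  "carbons": "1-7", "instrument": "icms_sugarP"},
    {"fragment_id": "F6P[1-6]", "metabolite": "F6P",  "carbons": "1-6", "instrument": "icms_sugarP"},
    {"fragment_id": "G6P[1-6]", "metabolite": "G6P",  "carbons": "1-6", "instrument": "icms_sugarP"},
    {"fragment_id": "6PG[1-6]", "metabolite": "6PG",  "carbons": "1-6", "instrument": "icms_sugarP"}
  ]
}
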