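{
  "id": "toy_putida_core_synthetic",
  "description": "Hand-built synthetic toy genome-scale-style model for exercising the xylose surgery, MFA-derived bounds and cofactor accounting. Not a reconstruction of any organism.",
  "metabolites": [
    {"id": "glc__D_e", "name": "D-glucose", "compartment": "e", "formula": "C6H12O6"},
    {"id": "glc__D_p", "name": "D-glucose", "compartment": "p", "formula": "C6H12O6"},
    {"id": "glc__D_c", "name": "D-glucose", "compartment": "c", "formula": "C6H12O6"},
    {"id": "glcn_p", "name": "D-gluconate", "compartment": "p", "formula": "C6H12O7"},
    {"id": "xu5p__D_c", "name": "D-xylulose 5-phosphate", "compartment": "c", "formula": "C5H9O8P"},
    {"id": "pyr_c", "name": "pyruvate", "compartment": "c", "formula": "C3H3O3"},
    {"id": "co2_c", "name": "CO2", "compartment": "c", "formula": "CO2"},
    {"id": "co2_e", "name": "CO2", "compartment": "e", "formula": "CO2"},
    {"id": "nadh_c", "name": "NADH", "compartment": "c"},
    {"id": "nadph_c", "name": "NADPH", "compartment": "c"},
    {"id": "atp_c", "name": "ATP", "compartment": "c", "formula": "C10H12N5O13P3"},
    {"id": "adp_c", "name": "ADP", "compartment": "c", "formula": "C10H12N5O10P2"},
    {"id": "h_c", "name": "proton", "compartment": "c", "formula": "H"},
    {"id": "h_p", "name": "proton", "compartment": "p", "formula": "H"}
  ],
  "reactions": [
    {"id": "EX_glc__D_e", "name": "glucose exchange", "metabolites": {"glc__D_e": -1}, "lower_bound": 0, "upper_bound": 1000},
    {"id": "GLCtex", "name": "glucose diffusion (outer membrane)", "metabolites": {"glc__D_e": -1, "glc__D_p": 1}, "lower_bound": -1000, "upper_bound": 1000},
    {"id": "GCD", "name": "periplasmic glucose dehydrogenase", "metabolites": {"glc__D_p": -1, "glcn_p": 1}, "lower_bound": 0, "upper_bound": 1000},
    {"id": "DM_glcn_p", "name": "gluconate sink", "metabolites": {"glcn_p": -1}, "lower_bound": 0, "upper_bound": 1000},
    {"id": "GLCt2pp", "name": "glucose proton symport", "metabolites": {"glc__D_p": -1, "h_p": -1, "glc__D_c": 1, "h_c": 1}, "lower_bound": 0, "upper_bound": 1000},
    {"id": "GLYC", "name": "glycolysis (lumped)", "metabolites": {"glc__D_c": -1, "adp_c": -2, "pyr_c": 2, "atp_c": 2, "nadh_c": 2}, "lower_bound": 0, "upper_bound": 1000},
    {"id": "PPP", "name": "pentose route to pyruvate (lumped)", "metabolites": {"xu5p__D_c": -1, "adp_c": -1, "pyr_c": 1.5, "co2_c": 0.5, "atp_c": 1, "nadph_c": 2, "nadh_c": 1}, "lower_bound": 0, "upper_bound": 1000},
    {"id": "OXID", "name": "pyruvate full oxidation (lumped)", "metabolites": {"pyr_c": -1, "co2_c": 3, "nadh_c": 4}, "lower_bound": 0, "upper_bound": 1000},
    {"id": "RESP", "name": "oxidative phosphorylation (lumped)", "metabolites": {"nadh_c": -1, "adp_c": -2, "atp_c": 2}, "lower_bound": 0, "upper_bound": 1000},
    {"id": "THD1", "name": "transhydrogenase A", "metabolites": {"nadh_c": -1, "nadph_c": 1}, "lower_bound": 0, "upper_bound": 1000},
    {"id": "THD2", "name": "transhydrogenase B", "metabolites": {"nadh_c": -1, "nadph_c": 1}, "lower_bound": 0, "upper_bound": 1000},
    {"id": "NADPHD", "name": "NADPH demand", "metabolites": {"nadph_c": -1}, "lower_bound": 0, "upper_bound": 1000},
    {"id": "NADHD", "name": "NADH demand", "metabolites": {"nadh_c": -1}, "lower_bound": 0, "upper_bound": 1000},
    {"id": "ATPM", "name": "ATP maintenance", "metabolites": {"atp_c": -1, "adp_c": 1}, "lower_bound": 0, "upper_bound": 1000},
    {"id": "CO2tpp", "name": "CO2 diffusion", "metabolites": {"co2_c": -1, "co2_e": 1}, "lower_bound": -1000, "upper_bound": 1000},
    {"id": "EX_co2_e", "name": "CO2 exchange", "metabolites": {"co2_e": -1}, "lower_bound": -1000, "upper_bound": 1000},
    {"id": "EX_h_p", "name": "periplasmic proton pool", "metabolites": {"h_p": -1}, "lower_bound": -1000, "upper_bound": 1000},
    {"id": "DM_h_c", "name": "cytosolic proton sink", "metabolites": {"h_c": -1}, "lower_bound": 0, "upper_bound": 1000},
    {"id": "BIOMASS_toy", "name": "biomass formation", "metabolites": {"pyr_c": -3, "atp_c": -10, "adp_c": 10}, "lower_bound": 0, "upper_bound": 1000, "objective_coefficient": 1}
  ],
  "genes": []
}
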