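kind,category,rules_version,note
extracellular_mucin,stroma,2022-proposal,"All extracellular mucin pools counted as stroma, including colloid carcinoma"
neoplastic_cells_in_mucin,viable_tumor,2022-proposal,"Residual neoplastic cells within mucin are viable tumor; the surrounding mucin remains stroma"
fibrovascular_core,stroma,2022-proposal,"Fibrovascular cores of papillary tumors counted as stroma across all histologic subtypes"
native_or_regressive_fibrosis,stroma,2022-proposal,"No distinction attempted between native stroma and the regression bed"
inflammation,stroma,2022-proposal,"Inflammation is part of stroma (fibrosis plus inflammation)"
necrosis_focus,necrosis,2022-proposal,"Necrotic foci are the necrosis component"
empty_cystic_cavity,excluded_from_bed,2022-proposal,"Empty cystic cavities meet no component's criteria; area subtracted from the tumor-bed denominator"
bronchial_lumen,excluded_from_bed,2022-proposal,"Sizable empty spaces such as bronchial lumina subtracted from the tumor bed"
nodal_direct_extension,viable_tumor,2022-proposal,"Direct tumor extension into a hilar lymph node is viable tumor bed (N1 for staging, bed for response)"
nodal_metastasis_encapsulated,not_primary_bed,2022-proposal,"A metastasis with a well-defined intact capsule is a nodal deposit, not primary tumor bed"
viable_tumor_cells,viable_tumor,2022-proposal,"Viable tumor cells are viable tumor"
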