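# Medication-based comorbidity proxy (RxRisk-style): a claim for a drug
# carrying one of the listed class tags flags the category.  Simplified
# lookup covering the 12 categories used as regression covariates.
categories:
  - {category: anxiety_tension, display_name: "Anxiety & Tension", class_tags: [benzodiazepine, anxiolytic]}
  - {category: asthma, display_name: "Asthma", class_tags: [beta_agonist_inhaled, inhaled_corticosteroid, xanthine]}
  - {category: cardiac_disease, display_name: "Cardiac Disease", class_tags: [antiarrhythmic, cardiac_glycoside]}
  - {category: coronary_peripheral_vascular, display_name: "Coronary/Peripheral Vascular Disease", class_tags: [antiplatelet, anticoagulant, nitrate]}
  - {category: depression, display_name: "Depression", class_tags: [ssri, snri]}
  - {category: diabetes, display_name: "Diabetes", class_tags: [biguanide, insulin]}
  - {category: epilepsy, display_name: "Epilepsy", class_tags: [anticonvulsant]}
  - {category: end_stage_renal_disease, display_name: "End Stage Renal Disease", class_tags: [phosphate_binder]}
  - {category: glaucoma, display_name: "Glaucoma", class_tags: [ophthalmic_beta_blocker, prostaglandin_ophthalmic]}
  - {category: heart_disease_hypertension, display_name: "Heart Disease/Hypertension", class_tags: [ace_inhibitor, calcium_channel_blocker, thiazide, beta_blocker]}
  - {category: hyperlipidemia, display_name: "Hyperlipidemia", class_tags: [statin, fibrate, cholesterol_absorption_inhibitor, niacin]}
  - {category: irritable_bowel_syndrome, display_name: "Irritable Bowel Syndrome", class_tags: [antispasmodic]}
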