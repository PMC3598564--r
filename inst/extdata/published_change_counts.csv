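rule_id,n_per_arm,changes_intervention,changes_control,published_p
warfarin_statins,939,9,10,0.82
statins_azoles,247,2,2,1.0
warfarin_fibrates,303,55,48,0.45
simvastatin_amiodarone,169,8,3,0.13
statins_macrolides,140,41,42,0.89
benzodiazepines_azoles,86,9,4,0.15
warfarin_azoles,62,1,1,1.0
ciprofloxacin_tizanidine,24,13,11,0.56
isotretinoin_tetracyclines,15,1,1,1.0
amiodarone_macrolides,11,2,4,0.63
theophylline_quinolones,12,8,2,0.04
amiodarone_quinolones,7,3,2,1.0
carbamazepine_macrolides,4,2,2,1.0
total,2019,154,132,0.177
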