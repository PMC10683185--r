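species,dipole_debye,energy_kcal,binding_energy_kcal,note
BNNT,13.72,-4957999.32,NA,
SSZ_enol,5.24,-1058804.12,NA,
SSZ_keto,7.91,-1058794.61,NA,
enol_carbonyl_v1,13.52,-6016807.22,-3.78,
enol_carbonyl_v2,7.71,-6016802.45,-2.27,known_discrepancy: printed total energy equals the sulfonamide row and is inconsistent with this binding energy
enol_sulfonamide,14.96,-6016802.45,0.99,
keto_carbonyl_v1,21.78,-6016812.11,-18.18,
keto_carbonyl_v2,22.68,-6016818.58,-24.64,
keto_sulfonamide,21.27,-6016810.92,-16.99,
keto_pyridine,14.49,-6016799.32,-5.39,
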