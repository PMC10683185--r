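species,dg_sol_printed,dg_sol,dg_ass,printed_decimals,note
BNNT,-248.2917,-248.2917,NA,4,
SSZ_enol,-21.134,-21.134,NA,3,
SSZ_keto,-21.7606,-21.7606,NA,4,
enol_carbonyl_v1,-223.0949,-223.0949,-46.3308,4,
enol_carbonyl_v2,-223.4236,-223.4236,-46.0021,4,
enol_sulfonamide,-220.2629,-220.2629,-49.1628,4,
keto_carbonyl_v1,234.464,-234.464,-35.5883,4,sign_typo: leg printed without minus; corrected value in dg_sol reproduces the printed dg_ass
keto_carbonyl_v2,-225.7073,-225.7073,-44.345,3,
keto_sulfonamide,-222.5613,-222.5613,-47.491,3,
keto_pyridine,-206.97,-206.97,-63.08,2,dg_ass printed to 2 decimals only
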