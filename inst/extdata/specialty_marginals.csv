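category,count
Cancer,905
Cardiovascular,1693
Central nervous system/musculoskeletal,1965
"Digestive/endocrine, nutritional and metabolic",2704
"Gynaecology, pregnancy and birth",4656
Infectious diseases,965
Mental health and behavioural conditions,2918
"Pathological conditions, symptoms and signs",701
Respiratory diseases,3021
Urogenital,1289
Other,1637
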