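active,Control,Placebo,Pharmacological,same-category non-pharm,different-category non-pharm
Pharmacological,4027,4321,5571,NA,186
Vaccines,95,113,0,49,0
Surgical,241,2,29,1204,86
Medical devices,706,50,82,941,159
Cellular and gene,29,6,0,57,7
Radiotherapy,124,65,3,56,63
Physical,318,10,8,72,39
Educational,303,4,1,34,27
Behavioural,380,7,3,165,14
Screening,17,0,0,0,0
Complementary,216,104,41,8,19
Psychological,379,1,6,116,44
Resources and infrastructure,506,0,14,52,33
Complex,505,36,43,200,154
Other,188,44,8,51,11
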