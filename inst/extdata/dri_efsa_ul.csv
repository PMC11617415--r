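sex,age_lo,age_hi,ear_mg,ul_mg
ALL,1,4,500,2500
ALL,4,9,800,2500
F,9,14,1100,3000
M,9,14,1100,3000
F,14,19,1100,3000
M,14,19,1100,3000
F,19,31,800,2500
M,19,31,800,2500
F,31,51,800,2500
M,31,51,800,2500
F,51,71,1000,2500
M,51,71,800,2500
F,71,,1000,2500
M,71,,1000,2500
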