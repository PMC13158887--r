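date,age,method,external_uCi,breath_uCi,retained_fraction,flag
1957-10-23,49,tilting_chair,0.650,,0.31,
1962-10-02,54,tilting_chair,0.558,,0.31,
1962-12-12,54,tilting_chair,0.570,,0.31,
1962-12-12,54,seven_crystal,0.556,,0.31,
1966-10-03,58,tilting_chair,0.537,,0.31,
1966-10-03,58,seven_crystal,0.620,,0.31,
1973-02-02,64,rn_breath_plus_external,0.548,1.024,,
1974-04-30,65,rn_breath_plus_external,0.510,0.659,,breath measurement possibly biased low due to facial paralysis
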