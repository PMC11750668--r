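sex,body_mass_kg,required_exogenous_rate_g_per_hr
male,50,70
male,54,82
male,58,105
male,62,120
female,42,90
female,46,103
female,50,114
female,54,128
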