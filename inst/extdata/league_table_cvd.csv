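intervention,halys_per_1000,ui_lo,ui_hi
Persistent dietary advice (adults 5-9% 5yr CVD risk),0.017,0.010,0.027
Persistent lifestyle program (adults 5-9% 5yr CVD risk),0.024,0.010,0.027
Persistent Community Heart Health Program,0.141,0.071,0.221
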