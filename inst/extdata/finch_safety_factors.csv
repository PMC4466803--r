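species,behavior,model_force_base_N,model_force_tip_N,sf_base,sf_tip
G_fortis,base_crush,30,22,1.6,1
G_magnirostris,base_crush,58,42,1.1,0.7
G_fuliginosa,base_crush,7.1,4.6,2.5,1.6
G_conirostris,probe_and_crush,15,10,1.1,1
G_scandens,probe_and_crush,8.9,6.1,2,1.3
G_difficilis,probe_and_crush,3.6,2.4,2.1,2.3
C_olivacea,probe,2,1,1,1.4
C_parvulus,tip_crush,3.4,2.2,2.1,1.8
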