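model,rotation_time_s,n_sources,multisegment,weight
Definition,0.33,2,0,20
Definition_Flash,0.28,2,0,13
Sensation_64,0.33,1,1,13
Sensation_Cardiac,0.37,1,1,5
Definition_AS,0.30,1,0,4
Definition_AS_plus,0.30,1,0,1
Definition_AS_plus_ds,0.28,2,0,1
LightSpeed_VCT,0.35,1,0,40
Discovery_CT750_HD,0.35,1,0,3
Discovery_STE,0.35,1,1,1
Brilliance_64,0.40,1,0,11
iCT_256,0.27,1,1,5
Aquilion_64,0.40,1,1,6
Aquilion_64_ss,0.40,1,0,4
Aquilion_ONE,0.35,1,1,5
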