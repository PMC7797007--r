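sex,segment_id,v_at_60bpm_mm_s,slope_mm_s_per_bpm
M,LM,17,0.12
M,LAD_prox,18,0.13
M,LAD_mid,19,0.14
M,LAD_dist,20,0.15
M,D1,19,0.14
M,D2,19,0.14
M,LCx_prox,21,0.15
M,LCx_mid,22,0.16
M,LCx_dist,23,0.16
M,OM1,22,0.16
M,OM2,22,0.16
M,RCA_prox,26,0.18
M,RCA_mid,28,0.20
M,RCA_dist,27,0.19
M,R_PDA,24,0.17
F,LM,17.5,0.12
F,LAD_prox,18.5,0.13
F,LAD_mid,19.5,0.14
F,LAD_dist,20.5,0.15
F,D1,19.5,0.14
F,D2,19.5,0.14
F,LCx_prox,21.5,0.15
F,LCx_mid,22.5,0.16
F,LCx_dist,23.5,0.16
F,OM1,22.5,0.16
F,OM2,22.5,0.16
F,RCA_prox,26.5,0.18
F,RCA_mid,28.5,0.20
F,RCA_dist,27.5,0.19
F,R_PDA,24.5,0.17
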