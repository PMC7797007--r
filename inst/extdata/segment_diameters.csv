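sex,segment_id,diameter_mm
M,LM,4.5
M,LAD_prox,3.7
M,LAD_mid,2.9
M,LAD_dist,2.0
M,D1,2.3
M,D2,1.9
M,LCx_prox,3.4
M,LCx_mid,2.7
M,LCx_dist,2.0
M,OM1,2.4
M,OM2,1.9
M,RCA_prox,3.9
M,RCA_mid,3.4
M,RCA_dist,2.8
M,R_PDA,2.1
F,LM,4.0
F,LAD_prox,3.3
F,LAD_mid,2.6
F,LAD_dist,1.8
F,D1,2.1
F,D2,1.7
F,LCx_prox,3.0
F,LCx_mid,2.4
F,LCx_dist,1.8
F,OM1,2.2
F,OM2,1.7
F,RCA_prox,3.5
F,RCA_mid,3.0
F,RCA_dist,2.5
F,R_PDA,1.9
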