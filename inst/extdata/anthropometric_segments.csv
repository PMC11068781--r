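segment,proximal_id,distal_id,mass_fraction,cm_ratio
head,1,0,0.0694,0.5
trunk,1,8,0.4346,0.4486
upper_arm_r,2,3,0.0271,0.5772
upper_arm_l,5,6,0.0271,0.5772
forearm_r,3,4,0.0162,0.4574
forearm_l,6,7,0.0162,0.4574
hand_r,4,4,0.0061,0
hand_l,7,7,0.0061,0
thigh_r,9,10,0.1416,0.4095
thigh_l,12,13,0.1416,0.4095
shank_r,10,11,0.0433,0.4459
shank_l,13,14,0.0433,0.4459
foot_r,24,22,0.0137,0.4415
foot_l,21,19,0.0137,0.4415
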