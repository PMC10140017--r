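quantity,IA1,IA2,IA3
q_bar_mls,4.38,4.53,2.55
f0_hz,1,1,1
venc_ms,1.1,1.2,1.2
density_kgm3,1142,1142,1142
kinematic_viscosity_m2s,4.67e-6,4.67e-6,4.67e-6
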