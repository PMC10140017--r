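quantity,IA1,IA2,IA3
max_height_mm,8.57,13.5,10.04
perpendicular_height_mm,8.31,12.93,6.99
max_width_mm,8.61,14.61,8.88
volume_mm3,314,1381,398
surface_mm2,220,593,273
inlet_parent_diameter_mm,3.35,3.43,1.52
neck_diameter_mm,6.72,9.55,11.62
aspect_ratio,1.24,1.35,0.88
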