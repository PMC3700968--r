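texture_class,porosity,field_capacity,wilting_point,sat_hydraulic_conductivity_mm_h,air_entry_potential_kpa,campbell_b,dry_conductivity_w_m_k,solids_conductivity_w_m_k,solids_heat_capacity_j_m3_k
sand,0.395,0.174,0.068,6336,1.187,4.05,0.238,5,2130000
loamy sand,0.41,0.179,0.075,5626.8,0.883,4.38,0.226,4.8,2130000
sandy loam,0.435,0.249,0.114,1227.6,2.138,4.9,0.208,4.3,2130000
loam,0.451,0.314,0.155,252,4.688,5.39,0.197,3.6,2130000
silt loam,0.485,0.369,0.179,259.2,7.708,5.3,0.177,3.1,2130000
sandy clay loam,0.42,0.299,0.175,226.8,2.932,7.12,0.219,3.4,2130000
clay loam,0.476,0.366,0.234,90,3.491,8.52,0.182,3,2130000
silty clay loam,0.477,0.384,0.235,61.2,6.178,7.75,0.181,2.8,2130000
sandy clay,0.426,0.316,0.219,79.2,1.5,10.4,0.214,3.2,2130000
silty clay,0.492,0.409,0.283,36,4.805,10.4,0.173,2.8,2130000
clay,0.482,0.4,0.286,46.8,3.972,11.4,0.179,2.5,2130000
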