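sample_id,patient_id,site,vessel_porosity_pct,lacunar_density_per_mm3,mineral_dist50_um,mineral_dist95_um,vessel_dist50_um,mineral_volume_mm3,vessel_dist95_um,sa_vv_per_mm,sa_tv_per_mm,sa_bv_per_mm
54A,54,AB,15.82,20228,98,226,29,17.5,120,22.8,2.6,2.9
54F,54,FB,3.82,18208,84,196,11,28.9,42,53.6,2.0,2.1
55A,55,AB,3.65,24108,93,205,10,3.7,43,60.5,2.2,2.3
55F,55,FB,5.84,17882,81,195,11,15.2,37,52.5,3.1,3.3
56A,56,AB,3.22,23984,93,188,9,13.5,31,59.7,1.9,2.0
56F,56,FB,6.38,21873,60,125,10,18.0,33,57.2,3.6,3.9
57A,57,AB,10.63,23175,101,213,26,25.3,92,23.1,2.5,2.8
57F,57,FB,11.62,19541,78,179,22,21.8,76,28.9,3.4,3.8
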