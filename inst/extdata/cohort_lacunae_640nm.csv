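sample_id,patient_id,site,n_lacunae,mineral_volume_mm3,lacunar_density_per_mm3,mean_lacuna_volume_um3,sd_lacuna_volume_um3,vessel_porosity_pct,r13_mean,r13_sd,r12_mean,r12_sd,r23_mean,r23_sd
54A,54,AB,55543,2.65,20978,627,295,11.27,2.9,0.7,2.2,0.7,1.3,0.2
54F,54,FB,85134,4.40,19354,698,280,2.91,3.2,0.8,2.2,0.7,1.5,0.3
55A,55,AB,33269,1.21,27470,414,183,2.07,2.8,0.9,2.1,0.7,1.4,0.3
55F,55,FB,48039,2.33,20625,657,268,3.63,3.1,1.0,2.1,0.7,1.5,0.3
56A,56,AB,59501,2.37,25136,303,145,3.41,3.4,1.2,2.6,1.0,1.4,0.2
56F,56,FB,14956,0.71,20975,604,306,6.90,2.7,0.8,2.0,0.7,1.4,0.2
63A,63,AB,16886,0.71,23860,559,254,1.07,3.2,0.9,2.4,0.8,1.4,0.3
63F,63,FB,32253,1.39,23279,541,237,4.87,2.8,0.7,2.2,0.7,1.3,0.2
67A,67,AB,10706,0.42,25647,431,174,9.18,2.8,0.8,2.2,0.7,1.4,0.2
67F,67,FB,35523,1.54,23068,555,251,7.24,2.9,0.8,2.2,0.7,1.3,0.2
68A,68,AB,59441,2.09,28416,851,325,1.03,3.1,0.8,2.4,0.8,1.3,0.2
68F,68,FB,22342,1.01,22186,466,185,5.21,2.7,0.7,2.0,0.7,1.4,0.3
69A,69,AB,36837,1.50,24508,685,315,8.11,3.1,0.8,2.3,0.8,1.4,0.3
69F,69,FB,32708,1.84,17807,688,299,8.48,3.0,0.8,2.1,0.7,1.5,0.3
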