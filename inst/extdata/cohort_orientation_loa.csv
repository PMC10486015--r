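sample_id,patient_id,site,s_phi,s_theta,loa_printed,loa_ratio_printed
54A,54,AB,5.17e-3,10.29e-3,5.32e-5,0.13
54F,54,FB,1.03e-3,6.73e-3,0.70e-5,NA
55A,55,AB,3.98e-3,6.32e-3,2.51e-5,0.61
55F,55,FB,2.85e-3,5.38e-3,1.53e-5,NA
56A,56,AB,1.12e-3,5.49e-3,0.62e-5,2.38
56F,56,FB,2.68e-3,5.50e-3,1.47e-5,NA
57A,57,AB,1.19e-3,8.47e-3,1.01e-5,2.71
57F,57,FB,4.82e-3,5.68e-3,2.74e-5,NA
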