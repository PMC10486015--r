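sample_id,patient_id,site,density_low_res,density_high_res
54A,54,AB,20228,20978
54F,54,FB,18208,19354
55A,55,AB,24108,27470
55F,55,FB,17882,20625
56A,56,AB,23984,25136
56F,56,FB,21873,20975
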