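sample_id,patient_id,site,ratio_EV_mean,invert_printed
54A,54,AB,0.0037,273.4
54F,54,FB,0.0024,425.5
55A,55,AB,0.0768,13.0
55F,55,FB,0.0171,58.5
56A,56,AB,0.0162,61.7
56F,56,FB,0.0338,29.6
57A,57,AB,0.1509,6.6
57F,57,FB,0.1237,8.1
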