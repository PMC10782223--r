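material_id,system,a,c,thermal_a0,thermal_slope,clamp_temperature,clamp_value
gold_fcc,cubic,4.0777,NA,4.0611,5.67075e-5,43,4.0636
gold_hcp,hexagonal,2.88,4.96,NA,NA,NA,NA
graphitized_carbon,cubic,5.92,NA,NA,NA,NA,NA
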