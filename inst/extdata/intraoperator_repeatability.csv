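quantity,plane,value_mm
avg_sd_manual,frontal,1.89
avg_sd_diff,frontal,0.45
avg_sd_manual,sagittal,3.64
avg_sd_diff,sagittal,0.06
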