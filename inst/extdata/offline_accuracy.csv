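subject,accuracy_mean_pct,accuracy_sd_pct
1,94.8,0.8
2,77.8,2.0
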