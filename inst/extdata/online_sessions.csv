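subject,session,xcorr,lag,omissions,false_alarms,fa_mean,fa_sd
1,1,0.771,10.25,0,1,12.00,NA
1,2,0.741,4.50,0,2,5.50,0.00
1,3,0.804,3.50,0,1,5.30,NA
1,4,0.861,4.50,0,0,NA,NA
1,5,0.870,12.00,0,0,NA,NA
2,1,0.781,6.25,0,1,8.80,NA
2,2,0.878,6.75,0,0,NA,NA
2,3,0.782,6.25,0,0,NA,NA
2,4,0.851,14.25,0,1,5.50,NA
2,5,0.785,5.75,0,2,8.40,4.10
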