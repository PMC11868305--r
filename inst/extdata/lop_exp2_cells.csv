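level,label,delay_hours,n,mean_dprime,se_dprime
deep,immediate,0,72,2.58,0.07
deep,30min,0.5,24,1.67,0.17
deep,2h,2,24,1.34,0.11
deep,24h,24,24,0.93,0.10
shallow,immediate,0,72,1.83,0.09
shallow,30min,0.5,24,1.02,0.16
shallow,2h,2,24,0.84,0.11
shallow,24h,24,24,0.59,0.12
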