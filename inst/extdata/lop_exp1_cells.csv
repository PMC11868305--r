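level,label,delay_hours,n,mean_dprime,se_dprime
deep,immediate,0,86,2.61,0.07
deep,30min,0.5,30,1.69,0.10
deep,2h,2,28,1.59,0.11
deep,24h,24,28,1.01,0.11
shallow,immediate,0,86,2.10,0.06
shallow,30min,0.5,30,1.21,0.10
shallow,2h,2,28,1.32,0.09
shallow,24h,24,28,0.61,0.10
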