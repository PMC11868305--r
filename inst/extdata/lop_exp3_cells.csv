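level,label,delay_hours,n,mean_dprime,se_dprime
deep,immediate,0,60,2.83,0.08
deep,30min,0.5,20,1.63,0.11
deep,2h,2,20,1.56,0.13
deep,6h,6,20,1.43,0.12
shallow,immediate,0,60,2.11,0.06
shallow,30min,0.5,20,1.22,0.15
shallow,2h,2,20,0.96,0.12
shallow,6h,6,20,0.66,0.08
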