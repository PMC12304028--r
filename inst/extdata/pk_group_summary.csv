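parameter,stat,bsa_ge_0.6,bsa_lt_0.6
n,count,22,4
Cmax,mean,1.456,1.256
Cmax,sd,0.384,0.146
tmax,median,1.74,1.78
tmax,min,1.42,1.63
tmax,max,48.6,5.0
AUC0_t,mean,402.0,375.2
AUC0_t,sd,92.837,51.628
AUC0_inf,mean,405.4,387.3
AUC0_inf,sd,85.753,55.135
t_half,mean,121.0,92.52
t_half,sd,100.16,22.964
CL,mean,0.006695,0.002463
CL,sd,0.0034763,0.00039535
Vss,mean,1.520,0.5584
Vss,sd,0.84159,0.059550
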