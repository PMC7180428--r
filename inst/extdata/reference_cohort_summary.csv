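parameter,mean,sd,n
cobb_deg,33.43,12.12,60
rho_deg,7.80,2.97,60
k_percent,62.68,4.36,60
a1,3.37,5.50,60
a2,13.95,5.94,60
a3,23.89,4.81,60
a4,29.97,3.40,60
a5,23.99,8.93,60
a6,4.83,2.15,60
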