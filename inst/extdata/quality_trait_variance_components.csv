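trait,sigma2_g,sigma2_e,H2,h2_snp
b_star,0.86,0.13,0.87,0.68
Wab,1.9,0.91,0.68,0.67
PSI,3.64,1.47,0.71,0.68
FlrYld,0.93,0.51,0.65,0.54
Protein,0.19,0.30,0.40,0.40
FSV,8.42,8.31,0.50,0.27
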