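trait,r_g,r_g_se,r_p,r_p_se
b_star,0.83,0.02,0.46,0.01
Wab,0.86,0.02,0.67,0.01
PSI,0.82,0.03,0.69,0.01
FlrYld,0.67,0.04,0.26,0.01
Protein,0.50,0.06,0.85,0.01
FSV,0.19,0.08,0.12,0.02
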