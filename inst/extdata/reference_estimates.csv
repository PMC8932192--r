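group,k,k_lo,k_hi,alpha,alpha_lo,alpha_hi,alpha_beta,ab_lo,ab_hi,ab_bca_lo,ab_bca_hi,x2
conventional,5.35,4.61,6.08,0.043,0.029,0.056,1.78,1.59,1.98,1.62,1.97,0.10
moderate_hypo,1.15,0.21,2.09,0.026,0.016,0.036,3.46,3.27,3.65,3.30,3.66,0.51
sbrt,1.67,-4.80,8.15,0.042,-0.27,0.36,4.24,4.10,4.39,4.14,4.34,0.01
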