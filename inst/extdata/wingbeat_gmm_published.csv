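bird_id,metric,mu1,sigma1,mu2,sigma2,xi1,xi2
2dg,frequency,9.78,1.61,17.26,1.01,0.5,0.5
2lg,frequency,10.26,1.83,18.14,0.91,0.5,0.5
2y,frequency,9.39,1.1,17.19,0.86,0.5,0.5
1y,frequency,8.97,0.6,15.76,0.96,0.5,0.5
3g,frequency,9.49,2.3,16.72,1,0.5,0.5
2dg,du_ratio,0.5,0.07,1.26,0.27,0.5,0.5
2lg,du_ratio,0.56,0.13,1.43,0.17,0.5,0.5
2y,du_ratio,0.48,0.07,1.26,0.27,0.5,0.5
1y,du_ratio,0.62,0.09,1.49,0.17,0.5,0.5
3g,du_ratio,0.48,0.12,1.3,0.17,0.5,0.5
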