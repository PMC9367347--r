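marker,breed,n,genotype1,freq1,genotype2,freq2,genotype3,freq3,allele1,allele1_freq,allele2,allele2_freq,hwe_verdict,pic,he,ne
g.T61908C,Qinchuan,658,CC,0.13,TC,0.61,TT,0.26,C,0.43,T,0.57,gt0.05,0.37,0.49,1.96
g.T61908C,Fu,52,CC,0.23,TC,0.56,TT,0.21,C,0.51,T,0.49,gt0.05,0.37,0.50,2.00
g.T61908C,Yak,48,CC,0.27,TC,0.58,TT,0.15,C,0.56,T,0.44,gt0.05,0.37,0.49,1.97
g.T61908C,Chaidam,69,CC,0.45,TC,0.35,TT,0.20,C,0.62,T,0.38,gt0.05,0.36,0.47,1.89
g.T62131C,Qinchuan,658,CC,0.39,TC,0.43,TT,0.18,C,0.61,T,0.39,gt0.05,0.36,0.48,1.91
g.T62131C,Fu,52,CC,0.28,TC,0.37,TT,0.35,C,0.47,T,0.53,gt0.05,0.37,0.50,1.99
g.T62131C,Yak,48,CC,0.80,TC,0.10,TT,0.10,C,0.84,T,0.16,lt0.01,0.23,0.27,1.37
g.T62131C,Chaidam,69,CC,0.29,TC,0.38,TT,0.33,C,0.48,T,0.52,gt0.05,0.37,0.50,2.00
g.C73406T,Qinchuan,658,CC,0.47,CT,0.43,TT,0.10,C,0.69,T,0.31,gt0.05,0.34,0.43,1.75
g.C73406T,Fu,52,CC,0.40,CT,0.33,TT,0.27,C,0.57,T,0.43,gt0.05,0.37,0.49,1.96
g.C73406T,Yak,48,CC,0.02,CT,0.44,TT,0.54,C,0.24,T,0.76,gt0.05,0.30,0.36,1.57
g.C73406T,Chaidam,69,CC,0.23,CT,0.55,TT,0.21,C,0.51,T,0.49,gt0.05,0.37,0.50,2.00
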