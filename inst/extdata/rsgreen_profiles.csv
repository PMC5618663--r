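name,lambda_ex,lambda_em,pKa,phi_fl,eps74,ecoli_brightness,hela_brightness
EGFP,489,509,5.9,0.60,52000,NA,NA
rsGreen1,487,508,6.2,0.46,65000,100,100
rsGreen1-Enhancer,486,505,4.4,0.47,78000,57,69
rsGreenF,488,510,6.8,0.42,52000,82,80
rsGreenF-Enhancer,485,506,5.6,0.37,71000,50,51
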