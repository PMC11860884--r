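name,normal_low,normal_high,pre_median,pre_q1,pre_q3,direction,unit
FBG,2,4,4.80,4.27,5.37,high-is-bad,g/L
PLT,125,350,279,216,363,high-is-bad,10^9/L
ESR,2,12,58,38,80,high-is-bad,mm/h
Hs-CRP,0,1,36,16,66,high-is-bad,mg/L
IgA,0.7,4,2.59,1.99,3.39,high-is-bad,g/L
IgG,7,16,12.8,10.2,15.9,high-is-bad,g/L
IgM,0.4,2.5,1.25,0.91,1.64,high-is-bad,g/L
RF,0,14,130,48,306,high-is-bad,U/mL
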