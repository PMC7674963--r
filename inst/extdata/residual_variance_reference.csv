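from,to,lp1,lp2,lp3,lp4,lp5
5,34,29.20,18.76,13.95,14.54,15.32
35,64,17.24,15.29,15.44,14.04,12.61
65,94,14.33,14.70,13.05,11.88,11.90
95,124,14.92,14.12,12.18,12.23,11.40
125,154,15.34,12.99,12.45,11.80,11.33
155,184,15.30,12.54,12.48,11.39,11.26
185,214,14.06,12.63,11.57,11.43,10.54
215,244,12.53,12.75,11.23,11.15,10.80
245,274,11.60,11.12,10.97,9.95,9.64
275,305,16.21,10.38,8.64,9.57,9.80
-1,-1,16.07,13.53,12.20,11.80,11.46
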