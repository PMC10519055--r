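angle_deg,min,max,median,mean_tttg_mm,sd
0,18.0,24.0,21.0,21.0,2.1
2,17.0,22.0,19.0,19.2,2.0
4,15.0,19.0,16.0,16.3,1.5
6,14.0,17.0,15.0,15.2,1.2
8,12.0,17.0,13.0,13.7,1.8
10,9.0,13.0,12.0,11.5,1.4
12,9.0,12.0,11.5,10.8,1.5
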