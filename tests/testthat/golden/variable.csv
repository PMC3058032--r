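well,template_name,primer_name,template_vol_ul,primer_vol_ul,mix_vol_ul,water_vol_ul
A1,pUC19,M13F,2.0,1.0,4.0,3.0
B1,pET28a-his,T7,1.0,1.0,4.0,4.0
C1,gDNA-k12,primF1,4.0,0.5,4.0,1.5
D1,pGEX-gst,primR9,0.8,0.1,4.0,5.1
G12,R.Control,,1.0,1.0,4.0,4.0
H12,I.Control,,1.0,1.0,4.0,4.0
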