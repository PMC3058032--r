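template_name,well,template_vol_ul,primer_name,primer_vol_ul,mix_vol_ul,water_vol_ul
pUC19,A1,2.0,M13F,1.0,4.0,3.0
pET28a-his,B1,1.0,T7,1.0,4.0,4.0
gDNA-k12,C1,4.0,primF1,0.5,4.0,1.5
pGEX-gst,D1,0.8,primR9,0.1,4.0,5.1
R.Control,G12,1.0,,1.0,4.0,4.0
I.Control,H12,1.0,,1.0,4.0,4.0
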