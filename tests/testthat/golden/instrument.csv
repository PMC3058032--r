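well,display_name,run_name,sample_ref
A1,pUC19_M13F,A1,S000001
B1,pET28a-his_T7,A1,S000002
C1,gDNA-k12_primF1,A1,S000003
D1,pGEX-gst_primR9,A1,S000004
G12,R.Control,A1,
H12,I.Control,A1,
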