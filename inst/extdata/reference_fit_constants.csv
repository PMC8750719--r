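Ta_K,Vdg_cm_s,A_s,B_s
270,100,0.38,0.86
270,20,0.5,1.25
220,100,0.12,0.15
220,20,0.21,0.23
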