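d_nozzle_mm,q_aog_lmin
1.5,0.315
3,1.555
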