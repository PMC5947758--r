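# hit         score
3pf8_A1        53.9
3pf8_B1        53.5
3pf9_A1        52.5
3pfb_A1        52.6
3pfb_B1        52.6
3pfc_A1        52.6
3qm1_A1        52.5
3s2z_A1        52.5
3s2z_B1        52.6
2wtn_B1        43.9
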