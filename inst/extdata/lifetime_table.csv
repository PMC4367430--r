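n0_1e16_cm3,experimental_us
4.2,3.15
1.8,3.61
0.8,3.92
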