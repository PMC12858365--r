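# Fitzpatrick skin tone -> epidermal melanosome volume fraction range
# (monotone increasing; Jacques-style ranges). version: 1
tone,mel_lo,mel_hi
1,0.010,0.020
2,0.020,0.040
3,0.040,0.080
4,0.080,0.130
5,0.130,0.200
6,0.200,0.300
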