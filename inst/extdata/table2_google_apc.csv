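keyword,total,ci_low,ci_high
coronavirus ozone,19,15,22
coronavirus laboratory,16,12,19
coronavirus 5G,10,8,13
coronavirus conspiracy,9,8,11
coronavirus bill gates,8,7,10
coronavirus milk,7,6,8
coronavirus military,4,4,5
coronavirus uv,3,3,4
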