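moniker,generic,misinformative,discriminatory,deviant,other
coronavirus ozone,1,2,0,0,2
coronavirus laboratory,2,2,1,2,2
coronavirus 5G,2,2,0,2,2
coronavirus conspiracy,2,2,1,2,2
coronavirus bill gates,1,1,0,2,2
coronavirus milk,2,2,0,2,2
coronavirus military,1,2,1,2,2
coronavirus uv,1,1,0,2,1
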