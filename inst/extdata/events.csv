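date,label,keyword
2020-03-25,National press agency posts 2015 video on virus origins,coronavirus laboratory
2020-04-04,Hydroxychloroquine touted as a miracle cure,tips and cures
2020-04-17,Nobel laureate claims laboratory-accident origin,coronavirus laboratory
2020-04-24,Disinfectant injection suggested as treatment,tips and cures
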