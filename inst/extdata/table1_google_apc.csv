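keyword,total,ci_low,ci_high
coronavirus,1378,1246,1537
corona,530,477,610
COVID,345,292,398
virus,239,212,292
corona virus,159,133,186
coronavirus Italy,54,45,62
COVID-19,53,45,60
coronavirus USA,32,29,36
coronavirus China,30,25,34
coronavirus Germany,23,20,27
corona Italy,13,12,14
corona Deutschland,12,10,14
SARS,9,8,10
corona China,9,7,11
corona Wuhan,1,0,2
SARS-CoV-2,1,0,1
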