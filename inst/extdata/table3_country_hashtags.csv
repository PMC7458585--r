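rank,country,count
1,Italy,963000
2,Brazil,551000
3,Spain,376000
4,Indonesia,298000
5,Turkey,244000
6,India,165000
7,Malaysia,89000
8,Dominican Republic,83000
9,United States,75000
10,Argentina,74000
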