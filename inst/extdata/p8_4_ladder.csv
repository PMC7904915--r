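fragment_dp,code,molar_amount
4,NS6S,1
4,2SNS6S,1
6,NS6S,1
6,2SNS6S,2
8,NS6S,1
8,2SNS6S,3
o3_udp4,2SNS6S,1
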