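"class","low","high"
"PARKS",0,0
"OTHER_PUBLIC",2e+05,6e+05
"PRIVATE_DEVELOPED",4e+06,8e+06
"PRIVATE_UNDEVELOPED",1e+06,3e+06
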