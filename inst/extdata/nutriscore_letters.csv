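category,letter,max_raw
general,A,-1
general,B,2
general,C,10
general,D,18
general,E,Inf
beverage,B,1
beverage,C,5
beverage,D,9
beverage,E,Inf
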