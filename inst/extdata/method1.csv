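"","A","B","C"
"A",0.7,0.03,0.27
"B",0.04,0.6,0.36
"C",0.065,0.585,0.35
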