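"id","true_cause","predicted_cause"
"d1","C","B"
"d2","C","B"
"d3","B","B"
"d4","A","A"
"d5","B","C"
"d6","A","C"
"d7","C","C"
"d8","B","C"
"d9","C","C"
"d10","C","B"
"d11","C","B"
"d12","A","A"
"d13","C","B"
"d14","A","A"
"d15","B","C"
"d16","A","A"
"d17","B","C"
"d18","B","C"
"d19","A","C"
"d20","C","B"
"d21","B","C"
"d22","A","A"
"d23","B","B"
"d24","A","C"
"d25","B","C"
"d26","B","B"
"d27","A","C"
"d28","B","B"
"d29","C","B"
"d30","C","C"
"d31","B","B"
"d32","A","A"
"d33","C","C"
"d34","C","C"
"d35","A","A"
"d36","B","B"
"d37","B","B"
"d38","B","B"
"d39","A","A"
"d40","A","A"
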