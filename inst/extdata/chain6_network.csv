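"","A","B","C","D","E","F"
"A","","4","","","",""
"B","","","4","","",""
"C","","","","4","",""
"D","","","","","4",""
"E","","","","","","4"
"F","","","","","",""
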