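"node","value"
"A",4
"B",0
"C",0
"D",0
"E",0
"F",0
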