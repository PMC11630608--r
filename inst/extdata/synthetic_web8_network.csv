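"","Policy","Predator","GrazerA","GrazerB","AlgaeTurf","AlgaeCanopy","FilterFeeder","Revenue"
"Policy","","4","","","","","",""
"Predator","","","-3","-2","","","","3"
"GrazerA","","","","-2","-4","","",""
"GrazerB","","","-2","","-2","","",""
"AlgaeTurf","","","","","","-1","",""
"AlgaeCanopy","","","","","-2","","1",""
"FilterFeeder","","","","","","","","2"
"Revenue","","","","","","","",""
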