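"id","node.type","node.name","Policy","Predator","GrazerA","GrazerB","AlgaeTurf","AlgaeCanopy","FilterFeeder","Revenue"
"s01",1,"Policy","","4","","","","","",""
"s02",2,"Predator","","","-3","-2","","","","3"
"s03",3,"GrazerA","","","","-2","-4","","",""
"s04",3,"GrazerB","","","-2","","-2","","",""
"s05",4,"AlgaeTurf","","","","","","-1","",""
"s06",4,"AlgaeCanopy","","","","","-2","","1",""
"s07",3,"FilterFeeder","","","","","","","","2"
"s08",1,"Revenue","","","","","","","",""
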