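"node","value"
"Policy",0
"Predator",-4
"GrazerA",0
"GrazerB",0
"AlgaeTurf",0
"AlgaeCanopy",0
"FilterFeeder",0
"Revenue",0
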