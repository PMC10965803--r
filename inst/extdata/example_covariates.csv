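"individual_id","Y","age","gender"
"S00001",1,60,1
"S00002",0,58.1,1
"S00003",0,68.8,1
"S00004",0,63,1
"S00005",1,55.1,0
"S00006",1,67.2,0
"S00007",1,66.7,1
"S00008",0,60.9,1
"S00009",1,57.7,1
"S00010",1,56.2,0
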