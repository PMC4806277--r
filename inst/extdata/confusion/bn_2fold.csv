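"","a","b","c","d","e","f","g","h","i","j","k","l"
"a",46,0,0,0,0,0,0,0,0,0,0,0
"b",0,45,0,0,0,0,0,0,1,0,0,0
"c",0,0,52,2,2,0,0,0,0,0,0,0
"d",0,2,1,32,0,1,0,0,1,0,0,0
"e",0,1,0,0,40,0,0,1,0,0,0,0
"f",0,0,0,0,0,54,0,0,0,1,0,1
"g",0,0,0,0,0,0,32,0,0,0,0,0
"h",0,1,0,1,0,0,0,48,0,2,0,0
"i",0,10,1,2,0,0,0,0,65,0,2,0
"j",0,0,0,0,0,1,0,0,0,63,0,0
"k",0,0,0,2,0,0,1,0,0,0,70,0
"l",1,1,0,2,0,0,1,0,1,1,0,27
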