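"","a","b","c","d","e","f","g","h","i","j","k","l"
"a",45,0,0,0,0,0,0,0,1,0,0,0
"b",0,41,0,0,0,0,0,0,5,0,0,0
"c",0,0,55,1,0,0,0,0,0,0,0,0
"d",0,2,1,31,0,0,0,0,3,0,0,0
"e",0,1,0,0,41,0,0,0,0,0,0,0
"f",0,0,0,0,0,55,0,0,0,1,0,0
"g",0,0,0,0,0,0,32,0,0,0,0,0
"h",0,0,0,0,0,0,0,51,0,1,0,0
"i",0,3,0,2,0,0,0,0,73,0,2,0
"j",0,0,0,0,0,0,0,0,0,64,0,0
"k",0,0,1,1,0,0,0,0,1,0,70,0
"l",0,0,0,0,0,0,1,0,0,1,0,32
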