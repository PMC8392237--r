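"code","suitability"
"1",0.4
"2",0.35
"3",1
"4",0.7
"5",0.9
"6",0.9
"7",0
"8",0.05
"9",0
"10",0.1
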