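"code","urban","rural","cropland","road1","road2"
"1",0.55,0.495,0.33,0.5225,0.4125
"2",0.5,0.45,0.3,0.475,0.375
"3",0.9,0.81,0.54,0.855,0.675
"4",0.7,0.63,0.42,0.665,0.525
"5",0.85,0.765,0.51,0.8075,0.6375
"6",0.85,0.765,0.51,0.8075,0.6375
"7",0,0,0,0,0
"8",0.1,0.09,0.06,0.095,0.075
"9",0,0,0,0,0
"10",0.3,0.27,0.18,0.285,0.225
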