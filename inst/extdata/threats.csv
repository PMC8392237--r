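"id","weight","d_max_m","decay"
"urban",1,8000,"exponential"
"rural",0.7,5000,"exponential"
"cropland",0.5,2000,"linear"
"road1",0.9,3000,"linear"
"road2",0.6,2000,"linear"
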