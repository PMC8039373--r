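item,theta1,theta2,theta3
CM015Q02D,1,0,0
CM015Q03D,1,0,0
CM020Q01,0,1,0
CM020Q02,0,1,0
CM020Q03,0,1,0
CM020Q04,0,1,0
CM038Q03T,0,0,1
CM038Q05,0,0,1
CM038Q06,0,0,1
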