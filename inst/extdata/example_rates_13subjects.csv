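subject,tpr,fpr,acc
1,0.87,0.34,0.77
2,0.62,0.18,0.74
3,1,0,1
4,0.81,0.3,0.76
5,0.67,0.05,0.89
6,0.67,0.2,0.74
7,1,0.15,0.92
8,0.34,0,0.67
9,1,0,1
10,0.95,0.17,0.88
11,1,0,1
12,0.3,0,0.65
13,0.91,0,0.96
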