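horseId,Walk,Trot,Tolt,Canter,FlyingPace,micro
1,1.0,1.0,1.0,1.0,NA,1.0
2,0.98,0.72,0.82,1.0,0.87,0.95
3,1.0,0.97,0.99,1.0,NA,0.99
4,0.83,0.82,0.96,0.61,NA,0.89
5,0.99,0.68,0.94,NA,NA,0.94
6,0.99,0.97,0.99,0.69,NA,0.98
7,1.0,0.88,0.92,0.99,NA,0.95
8,0.95,0.92,1.0,1.0,NA,0.97
9,0.93,0.88,1.0,1.0,NA,0.96
10,NA,NA,NA,NA,0.95,0.95
11,NA,NA,NA,NA,0.9,0.9
12,0.98,0.44,0.74,0.96,NA,0.87
13,0.97,0.0,0.98,NA,NA,0.97
14,1.0,1.0,1.0,1.0,NA,1.0
15,1.0,0.57,0.61,1.0,NA,0.82
16,0.97,0.66,0.5,1.0,NA,0.74
17,1.0,0.95,0.93,0.99,NA,0.94
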