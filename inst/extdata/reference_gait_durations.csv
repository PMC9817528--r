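horseId,Walk,Trot,Tolt,Canter,FlyingPace
1,1026,212,376,190,0
2,1488,98,253,39,85
3,767,427,973,154,0
4,470,416,935,42,0
5,394,121,710,0,0
6,1394,628,2275,88,0
7,1319,712,1161,257,0
8,354,192,496,63,0
9,157,120,212,32,0
10,0,0,0,0,28
11,0,0,0,0,27
12,155,55,67,40,0
13,144,0,338,0,0
14,141,90,144,102,0
15,124,61,100,14,0
16,117,41,80,24,0
17,134,80,134,38,0
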