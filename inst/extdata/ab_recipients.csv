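id,time,event
1,616,1
2,1124,0
3,387,0
4,968,0
5,726,0
6,1724,0
7,1600,0
8,1266,0
9,1092,0
10,1773,0
11,72,0
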