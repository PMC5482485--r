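item,option,A1,A2,A3,A4,A5
1,1,1,0,0,0,0
1,2,0,1,0,0,0
1,3,0,0,1,0,0
1,4,1,1,1,0,0
1,5,-1,-1,-1,0,0
2,1,1,0,0,0,0
2,2,0,1,0,0,0
2,3,0,0,0,0,1
2,4,1,1,0,0,1
2,5,-1,-1,0,0,-1
3,1,1,0,0,0,0
3,2,0,0,0,1,0
3,3,0,0,0,0,1
3,4,1,0,0,1,1
3,5,-1,0,0,-1,-1
4,1,0,1,0,0,0
4,2,0,0,1,0,0
4,3,0,0,0,1,0
4,4,0,1,1,1,0
4,5,0,-1,-1,-1,0
5,1,0,0,1,0,0
5,2,0,0,0,1,0
5,3,0,0,0,0,1
5,4,0,0,1,1,1
5,5,0,0,-1,-1,-1
6,1,1,0,0,0,0
6,2,0,0,1,0,0
6,3,0,0,0,1,0
6,4,1,0,1,1,0
6,5,-1,0,-1,-1,0
7,1,1,0,0,0,0
7,2,0,0,1,0,0
7,3,0,0,0,0,1
7,4,1,0,1,0,1
7,5,-1,0,-1,0,-1
8,1,1,0,0,0,0
8,2,0,0,0,1,0
8,3,0,0,0,0,1
8,4,1,0,0,1,1
8,5,-1,0,0,-1,-1
9,1,0,1,0,0,0
9,2,0,0,1,0,0
9,3,0,0,0,0,1
9,4,0,1,1,0,1
9,5,0,-1,-1,0,-1
10,1,0,1,0,0,0
10,2,0,0,0,1,0
10,3,0,0,0,0,1
10,4,0,1,0,1,1
10,5,0,-1,0,-1,-1
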