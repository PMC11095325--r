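"respondent","ext1","ext2","ext3","ext4","agr1","agr2","agr3","agr4","con1","con2","con3","con4"
1,3,4,0,0,4,2,3,0,4,0,4,0
2,0,1,4,0,1,1,2,0,3,4,2,1
3,2,4,0,2,0,3,3,4,1,4,0,4
4,2,1,0,1,3,4,3,2,4,3,2,4
5,1,4,1,4,1,3,1,2,3,0,1,1
6,0,1,3,2,1,0,3,2,3,0,0,4
7,1,1,2,3,3,3,2,3,4,3,4,0
8,0,3,0,3,1,4,0,4,1,2,4,2
9,2,1,4,0,1,2,4,0,3,1,3,1
10,1,1,4,0,2,0,2,2,4,0,1,4
11,1,4,0,3,1,4,1,1,0,2,2,2
12,1,3,4,0,1,1,3,3,2,1,1,0
13,2,4,1,2,3,3,1,0,0,2,3,2
14,2,1,4,2,1,3,1,1,0,4,2,3
15,0,4,0,3,2,3,4,2,0,0,2,0
16,4,2,2,2,2,0,1,0,3,2,2,1
17,3,4,0,4,0,2,1,4,2,1,4,1
18,2,4,1,2,3,0,4,2,0,4,3,1
19,1,2,0,1,4,0,3,1,3,2,3,1
20,3,3,3,1,2,0,2,1,3,0,3,0
21,1,2,4,1,1,2,2,3,3,1,4,1
22,2,2,1,2,4,4,3,2,3,1,3,0
23,0,3,1,1,2,3,1,4,4,4,4,0
24,4,2,1,4,4,3,2,0,1,1,0,1
25,2,4,3,0,2,2,2,3,1,3,1,1
26,4,1,4,2,3,0,1,3,4,4,4,1
27,4,4,0,2,4,2,3,3,3,1,1,4
28,2,0,4,0,3,3,4,0,4,1,0,3
29,3,3,0,2,3,1,4,1,2,3,3,0
30,4,1,1,4,1,1,1,1,3,1,1,0
31,1,1,0,3,3,2,3,4,4,4,1,3
32,2,2,0,2,1,2,1,3,1,0,4,4
33,1,0,2,0,4,0,3,0,4,4,4,2
34,3,3,3,1,3,1,4,0,1,2,2,4
35,2,1,1,1,1,3,2,4,0,3,3,4
36,4,3,2,0,4,0,4,4,2,4,0,1
37,3,0,3,2,1,4,2,4,2,1,2,2
38,0,1,4,3,0,2,0,4,1,3,0,1
39,3,2,4,1,0,2,1,1,0,0,0,4
40,1,1,0,2,2,0,1,1,1,4,4,4
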