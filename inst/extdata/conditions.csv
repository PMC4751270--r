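condition_id,game1,game2,strategy,trust
1,PD,PD,T4T,HT
2,PD,CG,T4T,HT
3,CG,PD,T4T,HT
4,CG,CG,T4T,HT
5,PD,PD,PT4T,HT
6,PD,CG,PT4T,HT
7,CG,PD,PT4T,HT
8,CG,CG,PT4T,HT
9,PD,PD,T4T,LT
10,PD,CG,T4T,LT
11,CG,PD,T4T,LT
12,CG,CG,T4T,LT
13,PD,PD,PT4T,LT
14,PD,CG,PT4T,LT
15,CG,PD,PT4T,LT
16,CG,CG,PT4T,LT
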