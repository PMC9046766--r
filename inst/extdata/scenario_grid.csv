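scenario,label,b_bar,sigma_AD,sigma_AI,sigma_AGR
1,competition,-0.05,0.015,0.015,1
2,neutral,0,0.015,0.015,1
3,cooperation,0.05,0.015,0.015,1
4,competition,-0.05,0.045,0.015,1
5,neutral,0,0.045,0.015,1
6,cooperation,0.05,0.045,0.015,1
7,competition,-0.05,0.005,0.015,1
8,neutral,0,0.005,0.015,1
9,cooperation,0.05,0.005,0.015,1
10,competition,-0.05,0.015,0.045,1
11,neutral,0,0.015,0.045,1
12,cooperation,0.05,0.015,0.045,1
13,competition,-0.05,0.015,0.005,1
14,neutral,0,0.015,0.005,1
15,cooperation,0.05,0.015,0.005,1
16,competition,-0.05,0.015,0.015,3
17,neutral,0,0.015,0.015,3
18,cooperation,0.05,0.015,0.015,3
19,competition,-0.05,0.015,0.015,0.3
20,neutral,0,0.015,0.015,0.3
21,cooperation,0.05,0.015,0.015,0.3
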