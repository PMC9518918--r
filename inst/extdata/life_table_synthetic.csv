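age,expectancy
0,88.9
1,88.0
5,84.0
10,79.1
15,74.1
20,69.1
25,64.2
30,59.2
35,54.3
40,49.3
45,44.4
50,39.6
55,34.9
60,30.3
65,25.7
70,21.3
75,17.1
80,13.2
85,9.8
90,6.9
95,4.8
100,3.3
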