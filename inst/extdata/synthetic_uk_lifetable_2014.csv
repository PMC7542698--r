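"age","q_all","deaths_all","deaths_c61"
50,0.003,300,6
51,0.00329567923775152,329,7
52,0.00362050054604882,360,7
53,0.00397733615996038,394,8
54,0.00436934140131326,431,9
55,0.00479998257965208,471,10
56,0.00527306764310945,515,11
57,0.00579277985021839,563,12
58,0.00636371476041004,615,13
59,0.00699092087028542,671,15
60,0.00767994425498781,732,16
61,0.00843687760941747,798,19
62,0.00926841412293595,870,21
63,0.0101819066639477,946,24
64,0.0111854327976987,1029,28
65,0.0122878662122135,1118,32
66,0.0134989551839535,1213,37
67,0.0148294087770313,1315,43
68,0.0162909915381974,1423,49
69,0.017896627524941,1537,57
70,0.0196605145865734,1659,66
71,0.021598249908827,1786,76
72,0.0237269679320966,1920,88
73,0.026065491862869,2059,100
74,0.0286345001180795,2203,113
75,0.0314567091741827,2351,126
76,0.0345570744377806,2502,140
77,0.0379630109140091,2653,153
78,0.0417046356239448,2804,165
79,0.0458150339146091,2952,176
80,0.0503305520164196,3094,186
81,0.055291118435029,3228,193
82,0.0607405970194619,3350,197
83,0.0667271748285574,3457,199
84,0.0733037882254309,3544,198
85,0.0805285909676957,3608,193
86,0.0884654684325398,3645,186
87,0.0971846025236947,3650,177
88,0.106763092255492,3620,165
89,0.117285635501525,3552,152
90,0.128845277936289,3444,138
91,0.141544235792317,3296,123
92,0.155494799708049,3109,108
93,0.170820327658716,2884,93
94,0.187656335750247,2627,79
95,0.20615169652154,2345,67
96,0.226469955351097,2045,55
97,0.248790776608374,1737,44
98,0.273311532337432,1434,35
99,0.300249047520843,1145,27
100,0.329841517356371,880,20
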