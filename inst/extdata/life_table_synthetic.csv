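age,annual_all_cause_probability
20,6.812572627563629e-4
21,6.983371094920754e-4
22,7.170251041085374e-4
23,7.374726268284393e-4
24,7.598453009938222e-4
25,7.843243318378379e-4
26,8.111079708286173e-4
27,8.404131173117557e-4
28,8.724770702620566e-4
29,9.075594441381174e-4
30,9.459442641235327e-4
31,9.879422574429197e-4
32,0.0010338933589751909
33,0.0010841694510498323
34,0.0011391773591319376
35,0.0011993621270726118
36,0.0012652105977523087
37,0.001337255327275244
38,0.0014160788634067778
39,0.0015023184216987895
40,0.0015966709957203618
41,0.0016998989410487164
42,0.0018128360761575646
43,0.0019363943471207845
44,0.0020715711071171983
45,0.0022194570661112634
46,0.002381244970804053
47,0.0025582390800173993
48,0.002751865506101403
49,0.0029636834987605276
50,0.0031953977538747846
51,0.0034488718364658055
52,0.003726142813907596
53,0.004029437202813124
54,0.0043611883407119745
55,0.004724055301643992
56,0.0051209434830854494
57,0.005555027000129109
58,0.006029773031477226
59,0.006548968270450373
60,0.0071167476427316245
61,0.007737625460741859
62,0.008416529192158517
63,0.009158836026823547
64,0.009970412431769105
65,0.01085765688785667
66,0.011827546003003508
67,0.012887684195465932
68,0.01404635713532465
69,0.015312589122152165
70,0.016696204560626926
71,0.018207893672132158
72,0.019859282547414536
73,0.02166300760113149
74,0.023632794431173942
75,0.02578354101118996
76,0.0281314050504633
77,0.03069389523739341
78,0.0334899659369029
79,0.036540114733127904
80,0.0398664819910487
81,0.0434929513478971
82,0.04744524973016506
83,0.051751045117073735
84,0.056440039828133504
85,0.06154405659219886
86,0.06709711404928043
87,0.07313548763568634
88,0.07969775099993115
89,0.08682479218502526
90,0.09455979778859813
91,0.10294819717631276
92,0.11203755758260125
93,0.12187741960064069
94,0.13251906116674494
95,0.14401517672395936
96,0.15641945686597203
97,0.1697860525003002
98,0.18416890654420148
99,0.1996209355295694
100,0.21619304343896084
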