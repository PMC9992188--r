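"slot_start_h","weight"
0,0.0917948647623594
0.5,0.0717195449379215
1,0.0573463256389274
1.5,0.0470620709542908
2,0.0397118361963522
2.5,0.0344692456856318
3,0.0307436884063884
3.5,0.028113915846177
4,0.0262805848258276
4.5,0.0250324096755385
5,0.024222110447266
5.5,0.0237494374505532
6,0.0235493395863352
6.5,0.0235839126085349
7,0.0238371768230313
7.5,0.0243120375351449
8,0.0250290090013032
8.5,0.0260264581452737
9,0.0273622661474575
9.5,0.0291169283187694
10,0.0313982268382322
10.5,0.0343477268079586
11,0.0381494728535184
11.5,0.0430414105072068
12,0.00625
12.5,0.00625
13,0.00625
13.5,0.00625
14,0.00625
14.5,0.00625
15,0.00625
15.5,0.00625
16,0.00625
16.5,0.00625
17,0.00625
17.5,0.00625
18,0.00625
18.5,0.00625
19,0.00625
19.5,0.00625
20,0.00625
20.5,0.00625
21,0.00625
21.5,0.00625
22,0.00625
22.5,0.00625
23,0.00625
23.5,0.00625
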