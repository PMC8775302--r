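length_cm,n
8,8.239956882406594e-6
9,4.884559524074892e-5
10,2.773018147829771e-4
11,0.0014774938741969896
12,0.007272889235588504
13,0.032716156268384235
14,0.13354207985143637
15,0.49243012783345486
16,1.635883653117804
17,4.887919673641066
18,13.123474100538612
19,31.646725976741838
20,68.53839468231097
21,133.35045534583153
22,233.25390261917607
23,367.2943099030074
24,521.8148934244427
25,671.289431893344
26,786.5339756292454
27,847.0068210733989
28,849.7723151012885
29,809.048065169202
30,746.7724944229659
31,680.8865911224367
32,618.7344070189491
33,558.2073219861803
34,493.7069941399939
35,421.95473603585305
36,344.4658355283077
37,266.5592715732802
38,194.6694976446223
39,133.86231554974975
40,86.57448263449903
41,52.63469516665355
42,30.075331027299214
43,16.14976999248448
44,8.149385175246652
45,3.8643824100204767
46,1.7219862022553811
47,0.7210614782731793
48,0.28373118676061865
49,0.10491393729323566
50,0.03645438715892506
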