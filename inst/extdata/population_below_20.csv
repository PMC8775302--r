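length_cm,n
8,24.968888682800955
9,85.45435409280168
10,229.92336909128747
11,488.0739503197106
12,823.189705105506
13,1118.857201265294
14,1259.9677642659174
15,1234.3683893355776
16,1123.4963459966252
17,997.7164321401257
18,859.9474445635973
19,687.96699894606
20,489.53786486702296
21,302.36758448408784
22,160.3924330347494
23,72.78086081880022
24,28.21426162817214
25,9.34034791667257
26,2.6402350967008155
27,0.6372071174200952
28,0.13129765423493164
29,0.023096810439789305
30,0.0034685292998403185
31,4.44647447108173e-4
32,4.865655380997713e-5
33,4.544639825099541e-6
34,3.6229945186923726e-7
35,2.464995228732779e-8
36,1.4316779332721913e-9
37,7.050139493042585e-11
38,3.3307745636421665e-12
39,0
40,0
41,0
42,0
43,0
44,0
45,0
46,0
47,0
48,0
49,0
50,0
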