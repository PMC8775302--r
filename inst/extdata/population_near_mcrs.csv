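length_cm,n
8,5.880900221631934e-6
9,6.185252535974821e-5
10,5.587341272234292e-4
11,0.004325835027471962
12,0.02866904868944738
13,0.16252808822340906
14,0.7878752784076447
15,3.2654873587821913
16,11.572734948476146
17,35.079209340582075
18,90.99892694206312
19,202.21688866718014
20,385.5620634055316
21,632.4535834940581
22,896.4980401993944
23,1106.2139195488785
24,1202.3065865602807
25,1171.6862933663192
26,1048.5095807607331
27,883.8569104407782
28,714.5295978029948
29,555.1107866937695
30,409.20356803441695
31,280.98409118183235
32,176.8516459012827
33,100.92550538985934
34,51.89676546637754
35,23.967507539072464
36,9.926092247301563
37,3.6838843538190282
38,1.2248341589578524
39,0.3647860459280475
40,0.09731170673171487
41,0.023251217980606812
42,0.004975902376645671
43,9.537542375995218e-4
44,1.637316984236868e-4
45,2.5174089479992195e-5
46,3.466509745965053e-6
47,4.275051424030191e-7
48,4.721645297029656e-8
49,4.670486220054259e-9
50,4.138911435856773e-10
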