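haul_id,length_cm,n_CD,n_CC,n_PC,q_CD,q_CC,q_PC
1,10,0,0,0,1,1,1
1,11,0,0,1,1,1,1
1,12,0,2,0,1,1,1
1,13,0,1,0,1,1,1
1,14,0,0,1,1,1,1
1,15,0,0,0,1,1,1
1,16,0,0,1,1,1,1
1,17,1,0,1,1,1,1
1,18,0,2,4,1,1,1
1,19,1,2,2,1,1,1
1,20,1,6,2,1,1,1
1,21,1,5,1,1,1,1
1,22,4,3,2,1,1,1
1,23,7,3,4,1,1,1
1,24,2,1,2,1,1,1
1,25,4,0,3,1,1,1
1,26,6,0,2,1,1,1
1,27,1,0,1,1,1,1
1,28,4,0,0,1,1,1
1,29,1,0,0,1,1,1
1,30,2,0,0,1,1,1
1,31,2,0,1,1,1,1
1,32,0,0,0,1,1,1
1,33,3,0,0,1,1,1
1,34,6,0,0,1,1,1
1,35,3,0,0,1,1,1
1,36,3,0,0,1,1,1
1,37,4,0,0,1,1,1
1,38,3,0,0,1,1,1
1,39,1,0,0,1,1,1
1,40,3,0,0,1,1,1
1,41,2,0,0,1,1,1
1,42,2,0,0,1,1,1
1,43,0,0,0,1,1,1
1,44,1,0,0,1,1,1
1,45,0,0,0,1,1,1
1,46,1,0,0,1,1,1
1,47,0,0,0,1,1,1
1,48,0,0,0,1,1,1
1,49,0,0,0,1,1,1
1,50,0,0,0,1,1,1
2,10,0,1,0,1,1,1
2,11,0,0,0,1,1,1
2,12,0,0,0,1,1,1
2,13,0,0,0,1,1,1
2,14,0,0,0,1,1,1
2,15,0,0,0,1,1,1
2,16,0,3,1,1,1,1
2,17,0,1,0,1,1,1
2,18,1,1,2,1,1,1
2,19,1,4,2,1,1,1
2,20,3,5,6,1,1,1
2,21,1,5,1,1,1,1
2,22,3,2,2,1,1,1
2,23,1,2,1,1,1,1
2,24,3,3,2,1,1,1
2,25,2,0,3,1,1,1
2,26,2,1,2,1,1,1
2,27,1,0,1,1,1,1
2,28,1,0,1,1,1,1
2,29,3,0,1,1,1,1
2,30,3,0,0,1,1,1
2,31,1,0,0,1,1,1
2,32,1,0,0,1,1,1
2,33,4,0,0,1,1,1
2,34,6,0,1,1,1,1
2,35,3,0,1,1,1,1
2,36,3,0,1,1,1,1
2,37,3,0,0,1,1,1
2,38,7,0,0,1,1,1
2,39,2,0,0,1,1,1
2,40,3,0,0,1,1,1
2,41,2,0,0,1,1,1
2,42,0,0,0,1,1,1
2,43,0,0,0,1,1,1
2,44,1,0,0,1,1,1
2,45,0,0,0,1,1,1
2,46,0,0,0,1,1,1
2,47,0,0,0,1,1,1
2,48,0,0,0,1,1,1
2,49,0,0,0,1,1,1
2,50,0,0,0,1,1,1
3,10,0,0,0,1,1,1
3,11,0,0,0,1,1,1
3,12,0,1,1,1,1,1
3,13,0,0,1,1,1,1
3,14,0,1,0,1,1,1
3,15,0,2,0,1,1,1
3,16,0,4,2,1,1,1
3,17,0,4,3,1,1,1
3,18,0,3,1,1,1,1
3,19,0,1,3,1,1,1
3,20,0,2,2,1,1,1
3,21,3,1,2,1,1,1
3,22,2,3,2,1,1,1
3,23,4,2,5,1,1,1
3,24,2,1,3,1,1,1
3,25,4,0,0,1,1,1
3,26,1,0,0,1,1,1
3,27,2,0,1,1,1,1
3,28,3,1,2,1,1,1
3,29,2,0,0,1,1,1
3,30,1,0,0,1,1,1
3,31,3,0,0,1,1,1
3,32,4,0,0,1,1,1
3,33,3,0,0,1,1,1
3,34,5,0,0,1,1,1
3,35,5,0,0,1,1,1
3,36,4,0,0,1,1,1
3,37,3,0,0,1,1,1
3,38,3,0,0,1,1,1
3,39,2,0,0,1,1,1
3,40,2,0,0,1,1,1
3,41,3,0,0,1,1,1
3,42,0,0,0,1,1,1
3,43,1,0,0,1,1,1
3,44,0,0,0,1,1,1
3,45,0,0,0,1,1,1
3,46,0,0,0,1,1,1
3,47,0,0,0,1,1,1
3,48,1,0,0,1,1,1
3,49,0,0,0,1,1,1
3,50,0,0,0,1,1,1
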