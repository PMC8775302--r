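haul_id,length_cm,n_CD,n_CC,n_PC,q_CD,q_CC,q_PC
1,10,0,0,2,1,1,1
1,11,0,2,1,1,1,1
1,12,0,0,0,1,1,1
1,13,0,3,2,1,1,1
1,14,0,3,2,1,1,1
1,15,0,4,4,1,1,1
1,16,1,9,2,1,1,1
1,17,0,11,7,1,1,1
1,18,3,10,6,1,1,1
1,19,2,16,16,1,1,1
1,20,0,12,15,1,1,1
1,21,5,16,11,1,1,1
1,22,13,7,15,1,1,1
1,23,7,10,9,1,1,1
1,24,9,2,13,1,1,1
1,25,6,2,3,1,1,1
1,26,15,2,7,1,1,1
1,27,12,0,6,1,1,1
1,28,8,1,3,1,1,1
1,29,18,0,3,1,1,1
1,30,8,0,1,1,1,1
1,31,15,1,1,1,1,1
1,32,13,0,0,1,1,1
1,33,17,1,1,1,1,1
1,34,7,0,0,1,1,1
1,35,13,0,0,1,1,1
1,36,21,0,3,1,1,1
1,37,15,0,1,1,1,1
1,38,16,0,0,1,1,1
1,39,8,0,0,1,1,1
1,40,8,0,0,1,1,1
1,41,6,0,0,1,1,1
1,42,3,0,0,1,1,1
1,43,1,0,0,1,1,1
1,44,2,0,0,1,1,1
1,45,1,0,0,1,1,1
1,46,0,0,0,1,1,1
1,47,0,0,0,1,1,1
1,48,0,0,0,1,1,1
1,49,0,0,0,1,1,1
1,50,0,0,0,1,1,1
2,10,0,0,0,1,1,1
2,11,0,0,0,1,1,1
2,12,0,1,3,1,1,1
2,13,0,1,2,1,1,1
2,14,0,4,3,1,1,1
2,15,0,3,3,1,1,1
2,16,0,7,8,1,1,1
2,17,0,5,5,1,1,1
2,18,1,16,10,1,1,1
2,19,0,14,14,1,1,1
2,20,2,16,12,1,1,1
2,21,5,16,19,1,1,1
2,22,5,15,10,1,1,1
2,23,7,7,8,1,1,1
2,24,11,6,7,1,1,1
2,25,6,7,4,1,1,1
2,26,15,3,8,1,1,1
2,27,11,3,9,1,1,1
2,28,7,1,2,1,1,1
2,29,9,3,4,1,1,1
2,30,6,0,2,1,1,1
2,31,15,0,6,1,1,1
2,32,11,0,4,1,1,1
2,33,12,0,0,1,1,1
2,34,9,1,1,1,1,1
2,35,17,0,0,1,1,1
2,36,14,0,0,1,1,1
2,37,11,0,0,1,1,1
2,38,10,0,0,1,1,1
2,39,13,0,0,1,1,1
2,40,15,0,0,1,1,1
2,41,3,0,0,1,1,1
2,42,4,0,0,1,1,1
2,43,0,0,0,1,1,1
2,44,2,0,0,1,1,1
2,45,1,0,0,1,1,1
2,46,0,0,0,1,1,1
2,47,2,0,0,1,1,1
2,48,0,0,0,1,1,1
2,49,0,0,0,1,1,1
2,50,0,0,0,1,1,1
3,10,0,0,0,1,1,1
3,11,0,0,0,1,1,1
3,12,0,0,2,1,1,1
3,13,0,5,0,1,1,1
3,14,1,2,2,1,1,1
3,15,0,4,3,1,1,1
3,16,0,8,7,1,1,1
3,17,0,5,4,1,1,1
3,18,0,17,9,1,1,1
3,19,1,4,13,1,1,1
3,20,2,10,10,1,1,1
3,21,6,18,7,1,1,1
3,22,7,18,9,1,1,1
3,23,5,15,11,1,1,1
3,24,9,6,8,1,1,1
3,25,9,5,5,1,1,1
3,26,8,3,2,1,1,1
3,27,13,2,6,1,1,1
3,28,9,1,3,1,1,1
3,29,5,1,1,1,1,1
3,30,11,1,5,1,1,1
3,31,15,0,3,1,1,1
3,32,15,0,3,1,1,1
3,33,12,0,3,1,1,1
3,34,16,1,0,1,1,1
3,35,12,0,0,1,1,1
3,36,16,0,0,1,1,1
3,37,18,0,0,1,1,1
3,38,15,0,0,1,1,1
3,39,11,0,0,1,1,1
3,40,10,0,0,1,1,1
3,41,4,0,0,1,1,1
3,42,3,0,0,1,1,1
3,43,1,0,0,1,1,1
3,44,0,0,0,1,1,1
3,45,2,0,0,1,1,1
3,46,0,0,0,1,1,1
3,47,0,0,0,1,1,1
3,48,0,0,0,1,1,1
3,49,0,0,0,1,1,1
3,50,0,0,0,1,1,1
4,10,0,0,0,1,1,1
4,11,0,0,1,1,1,1
4,12,0,0,1,1,1,1
4,13,0,4,0,1,1,1
4,14,0,3,2,1,1,1
4,15,0,4,2,1,1,1
4,16,0,8,5,1,1,1
4,17,1,8,7,1,1,1
4,18,0,8,8,1,1,1
4,19,0,14,10,1,1,1
4,20,1,19,12,1,1,1
4,21,3,11,14,1,1,1
4,22,4,17,21,1,1,1
4,23,7,21,9,1,1,1
4,24,4,6,6,1,1,1
4,25,8,7,11,1,1,1
4,26,8,7,7,1,1,1
4,27,8,6,2,1,1,1
4,28,13,0,1,1,1,1
4,29,4,1,3,1,1,1
4,30,12,0,2,1,1,1
4,31,7,1,4,1,1,1
4,32,16,0,1,1,1,1
4,33,13,0,5,1,1,1
4,34,12,0,4,1,1,1
4,35,15,0,0,1,1,1
4,36,18,0,2,1,1,1
4,37,14,0,1,1,1,1
4,38,21,0,1,1,1,1
4,39,8,0,0,1,1,1
4,40,7,0,0,1,1,1
4,41,7,0,0,1,1,1
4,42,6,0,0,1,1,1
4,43,4,0,0,1,1,1
4,44,2,0,0,1,1,1
4,45,1,0,0,1,1,1
4,46,1,0,0,1,1,1
4,47,1,0,0,1,1,1
4,48,0,0,0,1,1,1
4,49,0,0,0,1,1,1
4,50,0,0,0,1,1,1
5,10,0,0,1,1,1,1
5,11,0,1,0,1,1,1
5,12,0,0,0,1,1,1
5,13,0,6,0,1,1,1
5,14,0,3,3,1,1,1
5,15,0,6,1,1,1,1
5,16,0,5,6,1,1,1
5,17,0,7,1,1,1,1
5,18,2,7,5,1,1,1
5,19,2,17,11,1,1,1
5,20,5,4,9,1,1,1
5,21,3,22,7,1,1,1
5,22,11,6,10,1,1,1
5,23,13,5,15,1,1,1
5,24,13,3,16,1,1,1
5,25,9,1,9,1,1,1
5,26,11,2,8,1,1,1
5,27,12,0,3,1,1,1
5,28,5,0,2,1,1,1
5,29,10,0,1,1,1,1
5,30,9,0,3,1,1,1
5,31,13,0,2,1,1,1
5,32,15,1,0,1,1,1
5,33,12,0,0,1,1,1
5,34,13,0,1,1,1,1
5,35,19,0,1,1,1,1
5,36,17,0,1,1,1,1
5,37,14,0,1,1,1,1
5,38,13,0,0,1,1,1
5,39,11,1,0,1,1,1
5,40,12,0,0,1,1,1
5,41,6,0,0,1,1,1
5,42,10,0,0,1,1,1
5,43,3,0,0,1,1,1
5,44,5,0,0,1,1,1
5,45,2,0,0,1,1,1
5,46,1,0,0,1,1,1
5,47,0,0,0,1,1,1
5,48,1,0,0,1,1,1
5,49,0,0,0,1,1,1
5,50,0,0,0,1,1,1
6,10,0,0,0,1,1,1
6,11,0,1,0,1,1,1
6,12,0,4,1,1,1,1
6,13,0,1,3,1,1,1
6,14,0,3,0,1,1,1
6,15,0,5,3,1,1,1
6,16,0,7,8,1,1,1
6,17,0,9,6,1,1,1
6,18,1,9,7,1,1,1
6,19,1,16,17,1,1,1
6,20,1,15,10,1,1,1
6,21,6,8,5,1,1,1
6,22,8,12,8,1,1,1
6,23,13,15,8,1,1,1
6,24,13,4,10,1,1,1
6,25,13,5,4,1,1,1
6,26,14,2,4,1,1,1
6,27,9,3,1,1,1,1
6,28,11,0,3,1,1,1
6,29,12,1,6,1,1,1
6,30,14,1,1,1,1,1
6,31,13,1,0,1,1,1
6,32,16,0,4,1,1,1
6,33,18,0,2,1,1,1
6,34,19,0,0,1,1,1
6,35,14,0,1,1,1,1
6,36,14,0,2,1,1,1
6,37,9,0,1,1,1,1
6,38,9,0,0,1,1,1
6,39,13,0,0,1,1,1
6,40,8,0,0,1,1,1
6,41,7,0,0,1,1,1
6,42,0,0,0,1,1,1
6,43,2,0,0,1,1,1
6,44,1,0,0,1,1,1
6,45,3,0,0,1,1,1
6,46,0,0,0,1,1,1
6,47,1,0,0,1,1,1
6,48,1,0,0,1,1,1
6,49,0,0,0,1,1,1
6,50,0,0,0,1,1,1
7,10,0,0,0,1,1,1
7,11,0,1,0,1,1,1
7,12,0,1,3,1,1,1
7,13,0,2,1,1,1,1
7,14,0,2,4,1,1,1
7,15,0,2,4,1,1,1
7,16,0,6,2,1,1,1
7,17,0,6,1,1,1,1
7,18,0,12,8,1,1,1
7,19,5,14,5,1,1,1
7,20,3,10,11,1,1,1
7,21,5,10,9,1,1,1
7,22,11,6,11,1,1,1
7,23,13,6,7,1,1,1
7,24,12,2,13,1,1,1
7,25,12,1,3,1,1,1
7,26,10,3,6,1,1,1
7,27,11,0,6,1,1,1
7,28,12,0,1,1,1,1
7,29,9,0,2,1,1,1
7,30,11,1,2,1,1,1
7,31,15,0,4,1,1,1
7,32,17,0,1,1,1,1
7,33,16,0,0,1,1,1
7,34,21,0,2,1,1,1
7,35,15,0,1,1,1,1
7,36,24,0,0,1,1,1
7,37,9,0,0,1,1,1
7,38,10,0,1,1,1,1
7,39,11,0,0,1,1,1
7,40,12,0,0,1,1,1
7,41,5,0,0,1,1,1
7,42,10,0,0,1,1,1
7,43,0,0,0,1,1,1
7,44,2,0,0,1,1,1
7,45,1,0,0,1,1,1
7,46,0,0,0,1,1,1
7,47,0,0,0,1,1,1
7,48,1,0,0,1,1,1
7,49,0,0,0,1,1,1
7,50,0,0,0,1,1,1
8,10,0,1,0,1,1,1
8,11,0,0,0,1,1,1
8,12,0,0,2,1,1,1
8,13,0,3,1,1,1,1
8,14,0,4,3,1,1,1
8,15,0,5,5,1,1,1
8,16,0,7,6,1,1,1
8,17,1,9,6,1,1,1
8,18,1,13,6,1,1,1
8,19,0,20,8,1,1,1
8,20,1,15,17,1,1,1
8,21,4,16,10,1,1,1
8,22,10,19,11,1,1,1
8,23,6,15,8,1,1,1
8,24,2,10,3,1,1,1
8,25,7,8,5,1,1,1
8,26,13,0,11,1,1,1
8,27,8,2,6,1,1,1
8,28,5,0,7,1,1,1
8,29,8,0,2,1,1,1
8,30,11,1,6,1,1,1
8,31,11,0,5,1,1,1
8,32,12,0,3,1,1,1
8,33,14,0,1,1,1,1
8,34,12,0,0,1,1,1
8,35,16,0,0,1,1,1
8,36,15,0,1,1,1,1
8,37,8,0,1,1,1,1
8,38,13,0,0,1,1,1
8,39,7,0,1,1,1,1
8,40,12,0,0,1,1,1
8,41,5,0,0,1,1,1
8,42,9,0,0,1,1,1
8,43,10,0,0,1,1,1
8,44,2,0,0,1,1,1
8,45,1,0,0,1,1,1
8,46,2,0,0,1,1,1
8,47,2,0,0,1,1,1
8,48,0,0,0,1,1,1
8,49,0,0,0,1,1,1
8,50,1,0,0,1,1,1
9,10,0,0,0,1,1,1
9,11,0,0,1,1,1,1
9,12,0,0,0,1,1,1
9,13,0,3,0,1,1,1
9,14,0,2,1,1,1,1
9,15,0,1,3,1,1,1
9,16,0,5,2,1,1,1
9,17,0,11,5,1,1,1
9,18,2,5,12,1,1,1
9,19,6,9,11,1,1,1
9,20,5,12,8,1,1,1
9,21,6,11,13,1,1,1
9,22,14,10,15,1,1,1
9,23,14,8,11,1,1,1
9,24,10,1,10,1,1,1
9,25,13,4,11,1,1,1
9,26,18,0,8,1,1,1
9,27,16,0,3,1,1,1
9,28,15,0,2,1,1,1
9,29,12,0,1,1,1,1
9,30,15,0,1,1,1,1
9,31,8,0,1,1,1,1
9,32,10,1,1,1,1,1
9,33,14,0,2,1,1,1
9,34,17,0,1,1,1,1
9,35,16,0,1,1,1,1
9,36,17,0,2,1,1,1
9,37,11,0,1,1,1,1
9,38,3,0,0,1,1,1
9,39,8,0,0,1,1,1
9,40,11,0,0,1,1,1
9,41,9,0,1,1,1,1
9,42,6,0,0,1,1,1
9,43,1,0,0,1,1,1
9,44,5,0,0,1,1,1
9,45,1,0,0,1,1,1
9,46,3,0,0,1,1,1
9,47,1,0,0,1,1,1
9,48,0,0,0,1,1,1
9,49,0,0,0,1,1,1
9,50,2,0,0,1,1,1
10,10,0,0,0,1,1,1
10,11,0,0,0,1,1,1
10,12,0,1,1,1,1,1
10,13,1,3,4,1,1,1
10,14,0,4,2,1,1,1
10,15,0,5,3,1,1,1
10,16,0,7,1,1,1,1
10,17,0,7,6,1,1,1
10,18,1,11,7,1,1,1
10,19,4,16,17,1,1,1
10,20,3,12,9,1,1,1
10,21,6,11,7,1,1,1
10,22,10,11,7,1,1,1
10,23,9,6,13,1,1,1
10,24,13,4,4,1,1,1
10,25,12,0,7,1,1,1
10,26,18,5,4,1,1,1
10,27,11,3,3,1,1,1
10,28,20,1,2,1,1,1
10,29,11,0,2,1,1,1
10,30,6,0,2,1,1,1
10,31,15,0,2,1,1,1
10,32,16,0,1,1,1,1
10,33,19,1,0,1,1,1
10,34,17,0,0,1,1,1
10,35,14,0,0,1,1,1
10,36,20,0,1,1,1,1
10,37,14,0,0,1,1,1
10,38,17,0,0,1,1,1
10,39,11,0,0,1,1,1
10,40,8,0,0,1,1,1
10,41,6,0,0,1,1,1
10,42,3,0,0,1,1,1
10,43,3,0,0,1,1,1
10,44,3,0,0,1,1,1
10,45,2,0,0,1,1,1
10,46,0,0,0,1,1,1
10,47,4,0,0,1,1,1
10,48,1,0,0,1,1,1
10,49,0,0,0,1,1,1
10,50,0,0,0,1,1,1
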