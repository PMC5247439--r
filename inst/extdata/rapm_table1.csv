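subject_id,score,content,group
1,27,2D,HA
3,24,2D,HA
8,32,2D,HA
9,29,2D,HA
10,28,2D,HA
11,28,2D,HA
17,27,2D,HA
18,29,2D,HA
19,31,2D,HA
22,30,2D,HA
24,25,2D,HA
26,29,2D,HA
27,24,2D,HA
28,26,2D,HA
32,24,2D,HA
33,28,2D,HA
34,31,2D,HA
2,21,2D,LA
4,17,2D,LA
5,13,2D,LA
6,21,2D,LA
7,17,2D,LA
12,22,2D,LA
13,19,2D,LA
14,21,2D,LA
15,12,2D,LA
16,18,2D,LA
20,20,2D,LA
21,22,2D,LA
23,13,2D,LA
25,23,2D,LA
29,6,2D,LA
30,19,2D,LA
31,21,2D,LA
1,26,3D,HA
3,24,3D,HA
5,33,3D,HA
6,28,3D,HA
7,24,3D,HA
9,27,3D,HA
10,32,3D,HA
11,34,3D,HA
12,32,3D,HA
17,24,3D,HA
18,24,3D,HA
26,26,3D,HA
30,30,3D,HA
31,25,3D,HA
34,25,3D,HA
2,22,3D,LA
4,17,3D,LA
8,21,3D,LA
13,23,3D,LA
14,23,3D,LA
15,19,3D,LA
16,16,3D,LA
19,23,3D,LA
20,13,3D,LA
21,17,3D,LA
22,22,3D,LA
23,23,3D,LA
24,21,3D,LA
25,15,3D,LA
27,14,3D,LA
28,23,3D,LA
29,19,3D,LA
32,23,3D,LA
33,20,3D,LA
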