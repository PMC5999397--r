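sample_id,awi_bottom,awi_top,beh_bottom_center,beh_bottom_edge,beh_top_center,beh_top_edge,sat_bottom_center,sat_bottom_edge,sat_top_center,sat_top_edge,tilt_bottom_center,tilt_bottom_edge,tilt_top_center,tilt_top_edge,ice_bottom,ice_top
1,A,A,B1 or B2 or B3,B1 or B2 or B3,B1 or B2 or B3,B1 or B2 or B3,50,50,50,50,8,10,8,10,C2,C2
2,A,A,B1 or B2 or B3,--,B1 or B2 or B3,--,50,--,50,--,4-8,--,4-8,--,C1;C2,C1;C2
3,A,A,B1 or B2 or B3,--,B1 or B2 or B3,--,100,--,100,--,3-5,--,3-5,--,C2;C3,C2;C3
4,A2;A,A2;A,none,B3,none;B3,B3,--,40;40,--;50,50,3-7,5;3,3-7;7,5-7,C3;C4,C3;C4
5,A2,A2,B1 B3,--,B1 B3,--,30,--,30,--,1-5,--,1-5,--,C1;C2;C3,C1;C2;C3
6,A2,A2,B3,--,B3,--,80,--,80,--,6,--,6,--,C2,C2
7,A,A,B2 or B3,B2 or B3,B2 or B3,B2 or B3,50,50,70,70,1,3,1,3,C1;C2,C1;C2
8,A,A,B2 or B3,--,B2 or B3,--,50,--,50,--,0,--,0,--,C2;C3,C2;C3
9,A,A,B2 or B3,B2 or B3,B2 or B3,B2 or B3,60,60,60,40,7-10,8,7,9,C2;C3,C2;C3
10,A and A2,A2,B4 and B5,--,B4 and B5,--,1,--,50,--,10,--,10,--,C2,C2
11,A2,A2,B3 and B4 and B5,B3 and B4 and B5,B3 and B4 and B5,B3 and B4 and B5,70,70,70,70,7,7,7,7,--,--
12,A2,A2,B3,--,B3,--,80,--,1,--,0,--,0,--,C2;C3,C2;C3
13,A2,A2,B3,--,none,--,80,--,--,--,3-10,--,3-10,--,C2;C3,C2;C3
14,A2,A2,--,none;B3,--,B3;none,--,--;70,--,70;--,--,2-7;5,--,7;7,C3,C3
15,A,A,B2 or B3,B2 or B3,none;B2 or B3,none,60,50,--;60,--,2,4,2,11,C3,C3
16,A,A,B2 or B3,B2 or B3,B2 or B3,B2 or B3,90,90,90,90,6,9,6,1,C2,C3
17,A,A,B3,B3,B3,B3,70,80,70,80,4,10,4,11,C3,C3
18,A,A,B3,--,B3,--,50,--,60,--,10,--,4,--,C2;C3,C2;C3
19,A,A,none;B2,B3,none;B2,B3,--,--,--,--,3,11,5,11,C3;C4,C3;C4
20,A,A,B2 or B3,B2 or B3,B2 or B3,B2 or B3,70,60,70,60,3,--,3,--,C3,C3
21,A,A,B2 or B3,B2 or B3,B2 or B3,B2 or B3,90,80,90,80,3-9,6,3-9,10,C3,C3
22,A,A,B1 B2 or B3,B1 B2 or B3,B1 B2 or B3,B1 B2 or B3,90,90,90,90,5,5,5,5,C2;C3,C2;C3
23,A,A,B3,--,B3,--,40,--,40,--,0-3,--,0-3,--,C2;C3,C2;C3
24,A,A,B3,B3,B3,B3,80,60,80,60,2,4-6,2,4-9,C3,C3
25,A,A,B2,B2,B2,B2,80,80,80,80,8-10,8-10,8-10,8-10,C2;C3,C2;C3
26,A2,A2,B2 or B3 and B4 and B5,B1 B2 or B3 and B4 and B5,B2 or B3 and B4 and B5,B1 B2 or B3 and B4 and B5,50,50,50,50,0,5,0,2,C3,C3
27,A,A,B2 or B3,--,B2 or B3,--,95,--,95,--,0-4,--,0-4,--,C2,C2
28,A,A,B2 or B3,B2 or B3,B2 or B3,B2 or B3,80,70,80,70,5,3,5,7,C3,C3
29,A or A2,A or A2,B2 or B3,B2 or B3,B2 or B3,B2 or B3,70,50,70,50,7,13,7,9,C3,C3
30,A,A,B3,B1 B3,B3,B1 B3,70,50,70,50,10,1,10,16,C2,C3
31,A,A,B3,B1 B3,B3,B1 B3,40,40,40,40,--,10,--,2,C3,C2
32,A,A,B3,B1 B3,B3,B1 B3,40,40,30,30,4,7,4,6,C2,C3
33,A,A,B2 or B3,B2 or B3,B2 or B3,B2 or B3,90,90,<5,<5,1,4,1,1,C3,C2
34,A2,A2,B2 or B3,--,B2 or B3,--,50,--,50,--,4-6,--,4-6,--,C2;C3,C2;C3
35,A2,A2,B2 or B3,--,B2 or B3,--,60,--,60,--,4-12,--,4-12,--,C2;C3,C2;C3
36,A2,A2,B3,B1 B3,B3,B1 B3,50,50,70,60,5,10,5,3,C3,C3
37,A2,A2,B2 or B3,B1 B2 or B3,B2 or B3,B1 B2 or B3,50,50,40,30,4-7,6,4,4,C3,C3
38,A2,A2,B2 or B3,--,B2 or B3,--,20,--,20,--,5,--,1,--,C2;C3,C2;C3
39,A,A,B2 or B3,B1 B2 or B3,B2 or B3,B1 B2 or B3,40;50,40,40;50,40,--;3,5-9,--;3,2-8,C3,C3
40,Carbon,A,B1 B3,B1 B3,B3,B3,30;60,30;60,5,5,5,5-9,5,5,C2,C1;C2
41,A,Carbon,none,--,B1 B3,--,--,--,20;60,--,2-3,--,2-3,--,C2;C3,C2
42,A,A,B3,B1 B3,B3,B1 B3,80,5;80,80,5;20,3,14,3,3,C3,C2
43,A,A,B3,B3,B1 B3,B1 B3,10,10,20;90,20;95,2-5,2-5,5-7,5-7,C2,C3
44,A,A,B1 B3,--,B3,--,10;80,--,2,--,11,--,11,--,C3,C2
45,A,A,--,B1 B2 or B3,--,B1 B2 or B3,--,30,--,30,--,6,--,11,C3,C3
46,Streptavidin,Streptavidin,B2;none,B2,B2;none,B2,10-30;--,10-30,10-30;--,10-30,0;12,12,0;12,13-14,C1;C2;C3,C1;C2;C3
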