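1	133148
2	44321
3	14753
4	4911
5	1635
6	545
7	184
8	71
9	49
10	80
11	168
12	347
13	665
14	1187
15	1978
16	3091
17	4545
18	6313
19	8307
20	10383
21	12361
22	14047
23	15268
24	15905
25	15906
26	15294
27	14162
28	12647
29	10906
30	9094
31	7342
32	5749
33	4376
34	3249
35	2364
36	1702
37	1231
38	918
39	726
40	626
41	592
42	601
43	640
44	694
45	752
46	807
47	853
48	886
49	902
50	902
51	884
52	850
53	801
54	742
55	675
56	602
57	528
58	455
59	386
60	322
61	264
62	213
63	169
64	132
65	101
66	77
67	57
68	42
69	31
70	22
71	15
72	11
73	7
74	5
75	3
76	2
77	1
78	1
79	1
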