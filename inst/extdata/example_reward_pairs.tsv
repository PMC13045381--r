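# synthetic example: 127 atom-index pairs tagged by interdomain interface
68	341	MpD-CrD_A
167	337	MpD-CrD_A
129	410	MpD-CrD_A
162	319	MpD-CrD_A
43	327	MpD-CrD_A
14	319	MpD-CrD_A
210	343	MpD-CrD_A
187	420	MpD-CrD_A
51	386	MpD-CrD_A
85	369	MpD-CrD_A
21	420	MpD-CrD_A
106	339	MpD-CrD_A
182	343	MpD-CrD_A
74	324	MpD-CrD_A
7	418	MpD-CrD_A
73	419	MpD-CrD_A
79	369	MpD-CrD_A
37	338	MpD-CrD_A
105	350	MpD-CrD_A
110	341	MpD-CrD_A
165	305	MpD-CrD_A
34	323	MpD-CrD_A
106	331	MpD-CrD_A
126	313	MpD-CrD_A
89	301	MpD-CrD_A
172	344	MpD-CrD_A
207	317	MpD-CrD_A
33	321	MpD-CrD_A
84	377	MpD-CrD_A
163	401	MpD-CrD_A
70	364	MpD-CrD_A
74	414	MpD-CrD_A
104	347	MpD-CrD_B
70	406	MpD-CrD_B
70	363	MpD-CrD_B
104	393	MpD-CrD_B
103	405	MpD-CrD_B
75	395	MpD-CrD_B
209	402	MpD-CrD_B
13	359	MpD-CrD_B
40	350	MpD-CrD_B
176	392	MpD-CrD_B
89	333	MpD-CrD_B
23	309	MpD-CrD_B
110	300	MpD-CrD_B
84	342	MpD-CrD_B
103	358	MpD-CrD_B
29	325	MpD-CrD_B
141	314	MpD-CrD_B
150	357	MpD-CrD_B
156	328	MpD-CrD_B
108	323	MpD-CrD_B
48	341	MpD-CrD_B
33	347	MpD-CrD_B
45	416	MpD-CrD_B
149	375	MpD-CrD_B
31	338	MpD-CrD_B
102	323	MpD-CrD_B
145	352	MpD-CrD_B
73	391	MpD-CrD_B
87	385	MpD-CrD_B
83	339	MpD-CrD_B
118	396	MpD-CrD_B
90	382	MpD-CrD_B
90	350	MpD-StD_A
163	352	MpD-StD_A
43	315	MpD-StD_A
1	382	MpD-StD_A
29	399	MpD-StD_A
78	301	MpD-StD_A
150	347	MpD-StD_A
70	364	MpD-StD_A
28	343	MpD-StD_A
116	402	MpD-StD_A
37	404	MpD-StD_A
61	376	MpD-StD_A
174	389	MpD-StD_A
113	397	MpD-StD_A
195	365	MpD-StD_A
86	318	MpD-StD_A
71	316	MpD-StD_A
110	333	MpD-StD_A
99	374	MpD-StD_A
51	330	MpD-StD_A
44	334	MpD-StD_A
49	398	MpD-StD_A
105	345	MpD-StD_A
60	318	MpD-StD_A
184	408	MpD-StD_A
49	374	MpD-StD_A
50	315	MpD-StD_A
135	339	MpD-StD_A
111	308	MpD-StD_A
20	349	MpD-StD_A
121	391	MpD-StD_A
152	323	MpD-StD_A
138	383	MpD-StD_B
207	405	MpD-StD_B
160	409	MpD-StD_B
167	405	MpD-StD_B
165	356	MpD-StD_B
140	387	MpD-StD_B
126	416	MpD-StD_B
14	352	MpD-StD_B
116	385	MpD-StD_B
16	401	MpD-StD_B
15	349	MpD-StD_B
130	379	MpD-StD_B
65	329	MpD-StD_B
195	392	MpD-StD_B
201	301	MpD-StD_B
102	371	MpD-StD_B
17	377	MpD-StD_B
127	335	MpD-StD_B
133	389	MpD-StD_B
41	339	MpD-StD_B
108	416	MpD-StD_B
159	336	MpD-StD_B
117	371	MpD-StD_B
72	355	MpD-StD_B
36	370	MpD-StD_B
49	415	MpD-StD_B
41	399	MpD-StD_B
157	412	MpD-StD_B
64	405	MpD-StD_B
129	399	MpD-StD_B
53	420	MpD-StD_B
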