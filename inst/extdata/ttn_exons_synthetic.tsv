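exon_number	cds_start	cds_end	psi
1	1	223	1.00
2	224	446	1.00
3	447	669	1.00
4	670	892	1.00
5	893	1115	1.00
6	1116	1338	1.00
7	1339	1561	1.00
8	1562	1784	1.00
9	1785	2007	1.00
10	2008	2230	1.00
11	2231	2453	1.00
12	2454	2676	1.00
13	2677	2899	1.00
14	2900	3122	1.00
15	3123	3345	1.00
16	3346	3568	1.00
17	3569	3790	1.00
18	3791	4012	1.00
19	4013	4234	1.00
20	4235	4456	1.00
21	4457	4678	1.00
22	4679	4900	1.00
23	4901	5122	1.00
24	5123	5344	1.00
25	5345	5566	1.00
26	5567	5788	1.00
27	5789	6010	1.00
28	6011	6232	1.00
29	6233	6547	1.00
30	6548	6862	1.00
31	6863	7177	1.00
32	7178	7492	1.00
33	7493	7806	1.00
34	7807	8120	1.00
35	8121	8434	1.00
36	8435	8748	1.00
37	8749	9062	1.00
38	9063	9376	1.00
39	9377	9690	1.00
40	9691	10004	1.00
41	10005	10318	1.00
42	10319	10632	1.00
43	10633	10946	1.00
44	10947	11260	1.00
45	11261	11574	1.00
46	11575	11888	1.00
47	11889	12202	1.00
48	12203	12516	1.00
49	12517	12830	1.00
50	12831	13144	1.00
51	13145	13308	0.20
52	13309	13472	0.20
53	13473	13636	0.20
54	13637	13800	0.20
55	13801	13964	0.20
56	13965	14128	0.20
57	14129	14292	0.20
58	14293	14456	0.20
59	14457	14620	0.20
60	14621	14784	0.20
61	14785	14948	0.20
62	14949	15112	0.20
63	15113	15276	0.20
64	15277	15440	0.20
65	15441	15604	0.20
66	15605	15768	0.20
67	15769	15932	0.20
68	15933	16096	0.20
69	16097	16260	0.20
70	16261	16424	0.20
71	16425	16588	0.20
72	16589	16752	0.20
73	16753	16916	0.20
74	16917	17080	0.20
75	17081	17244	0.20
76	17245	17408	0.20
77	17409	17572	0.20
78	17573	17736	0.20
79	17737	17900	0.20
80	17901	18064	0.20
81	18065	18228	0.20
82	18229	18392	0.20
83	18393	18556	0.20
84	18557	18720	0.20
85	18721	18884	0.20
86	18885	19048	0.20
87	19049	19212	0.20
88	19213	19376	0.20
89	19377	19540	0.20
90	19541	19704	0.20
91	19705	19868	0.20
92	19869	20032	0.20
93	20033	20196	0.20
94	20197	20360	0.20
95	20361	20524	0.20
96	20525	20688	0.20
97	20689	20852	0.20
98	20853	21016	0.20
99	21017	21180	0.20
100	21181	21344	0.20
101	21345	21508	0.20
102	21509	21672	0.20
103	21673	21836	0.20
104	21837	22000	0.20
105	22001	22164	0.20
106	22165	22328	0.20
107	22329	22492	0.20
108	22493	22656	0.20
109	22657	22820	0.20
110	22821	22984	0.20
111	22985	23148	0.20
112	23149	23312	0.20
113	23313	23476	0.20
114	23477	23640	0.20
115	23641	23804	0.20
116	23805	23968	0.20
117	23969	24132	0.20
118	24133	24296	0.20
119	24297	24460	0.20
120	24461	24624	0.20
121	24625	24788	0.20
122	24789	24952	0.20
123	24953	25116	0.20
124	25117	25280	0.20
125	25281	25444	0.20
126	25445	25608	0.20
127	25609	25772	0.20
128	25773	25936	0.20
129	25937	26100	0.20
130	26101	26264	0.20
131	26265	26428	0.20
132	26429	26592	0.20
133	26593	26756	0.20
134	26757	26920	0.20
135	26921	27084	0.20
136	27085	27248	0.20
137	27249	27412	0.20
138	27413	27576	0.20
139	27577	27740	0.20
140	27741	27904	0.20
141	27905	28068	0.20
142	28069	28232	0.20
143	28233	28396	0.20
144	28397	28560	0.20
145	28561	28724	0.20
146	28725	28888	0.20
147	28889	29052	0.20
148	29053	29216	0.20
149	29217	29380	0.20
150	29381	29544	0.20
151	29545	29708	0.20
152	29709	29872	0.20
153	29873	30036	0.20
154	30037	30200	0.20
155	30201	30363	0.20
156	30364	30526	0.20
157	30527	30689	0.20
158	30690	30852	0.20
159	30853	31015	0.20
160	31016	31178	0.20
161	31179	31341	0.20
162	31342	31504	0.20
163	31505	31667	0.20
164	31668	31830	0.20
165	31831	31993	0.20
166	31994	32156	0.20
167	32157	32319	0.20
168	32320	32482	0.20
169	32483	32645	0.20
170	32646	32808	0.20
171	32809	32971	0.20
172	32972	33134	0.20
173	33135	33297	0.20
174	33298	33460	0.20
175	33461	33623	0.20
176	33624	33786	0.20
177	33787	33949	0.20
178	33950	34112	0.20
179	34113	34275	0.20
180	34276	34438	0.20
181	34439	34601	0.20
182	34602	34764	0.20
183	34765	34927	0.20
184	34928	35090	0.20
185	35091	35253	0.20
186	35254	35416	0.20
187	35417	35579	0.20
188	35580	35742	0.20
189	35743	35905	0.20
190	35906	36068	0.20
191	36069	36231	0.20
192	36232	36394	0.20
193	36395	36557	0.20
194	36558	36720	0.20
195	36721	36883	0.20
196	36884	37046	0.20
197	37047	37209	0.20
198	37210	37372	0.20
199	37373	37535	0.20
200	37536	37698	0.20
201	37699	37861	0.20
202	37862	38024	0.20
203	38025	38187	0.20
204	38188	38350	0.20
205	38351	38513	0.20
206	38514	38676	0.20
207	38677	38839	0.20
208	38840	39002	0.20
209	39003	39165	0.20
210	39166	39328	0.20
211	39329	39491	0.20
212	39492	39654	0.20
213	39655	39817	0.20
214	39818	39980	0.20
215	39981	40143	0.20
216	40144	40306	0.20
217	40307	40469	0.20
218	40470	40632	0.20
219	40633	40795	0.20
220	40796	40982	1.00
221	40983	41169	1.00
222	41170	41356	1.00
223	41357	41543	1.00
224	41544	41730	1.00
225	41731	41917	1.00
226	41918	42104	1.00
227	42105	42291	1.00
228	42292	42478	1.00
229	42479	42665	1.00
230	42666	42852	1.00
231	42853	43039	1.00
232	43040	43226	1.00
233	43227	43413	1.00
234	43414	43600	1.00
235	43601	43787	1.00
236	43788	43974	1.00
237	43975	44161	1.00
238	44162	44348	1.00
239	44349	44535	1.00
240	44536	44722	1.00
241	44723	44909	1.00
242	44910	45096	1.00
243	45097	45283	1.00
244	45284	45470	1.00
245	45471	45657	1.00
246	45658	45844	1.00
247	45845	46031	1.00
248	46032	46218	1.00
249	46219	46405	1.00
250	46406	46592	1.00
251	46593	46779	1.00
252	46780	46966	1.00
253	46967	47274	1.00
254	47275	47582	1.00
255	47583	47890	1.00
256	47891	48198	1.00
257	48199	48506	1.00
258	48507	48814	1.00
259	48815	49122	1.00
260	49123	49430	1.00
261	49431	49738	1.00
262	49739	50046	1.00
263	50047	50354	1.00
264	50355	50662	1.00
265	50663	50970	1.00
266	50971	51278	1.00
267	51279	51586	1.00
268	51587	51894	1.00
269	51895	52202	1.00
270	52203	52510	1.00
271	52511	52818	1.00
272	52819	53126	1.00
273	53127	53434	1.00
274	53435	53742	1.00
275	53743	54050	1.00
276	54051	54358	1.00
277	54359	54666	1.00
278	54667	54974	1.00
279	54975	55282	1.00
280	55283	55590	1.00
281	55591	55898	1.00
282	55899	56206	1.00
283	56207	56514	1.00
284	56515	56821	1.00
285	56822	57128	1.00
286	57129	57435	1.00
287	57436	57742	1.00
288	57743	58049	1.00
289	58050	58356	1.00
290	58357	58663	1.00
291	58664	58970	1.00
292	58971	59277	1.00
293	59278	59584	1.00
294	59585	59891	1.00
295	59892	60198	1.00
296	60199	60505	1.00
297	60506	60812	1.00
298	60813	61119	1.00
299	61120	61426	1.00
300	61427	61733	1.00
301	61734	62040	1.00
302	62041	62347	1.00
303	62348	62654	1.00
304	62655	62961	1.00
305	62962	63268	1.00
306	63269	63575	1.00
307	63576	63882	1.00
308	63883	64189	1.00
309	64190	64496	1.00
310	64497	64803	1.00
311	64804	65110	1.00
312	65111	65417	1.00
313	65418	65724	1.00
314	65725	66031	1.00
315	66032	66338	1.00
316	66339	66645	1.00
317	66646	66952	1.00
318	66953	67259	1.00
319	67260	67566	1.00
320	67567	67873	1.00
321	67874	68180	1.00
322	68181	68487	1.00
323	68488	68794	1.00
324	68795	69101	1.00
325	69102	69408	1.00
326	69409	69715	1.00
327	69716	86821	1.00
328	86822	87271	1.00
329	87272	87721	1.00
330	87722	88171	1.00
331	88172	88621	1.00
332	88622	89071	1.00
333	89072	89521	1.00
334	89522	89971	1.00
335	89972	90421	1.00
336	90422	90871	1.00
337	90872	91321	1.00
338	91322	91771	1.00
339	91772	92221	1.00
340	92222	92671	1.00
341	92672	93121	1.00
342	93122	93571	1.00
343	93572	94021	1.00
344	94022	94471	1.00
345	94472	94921	1.00
346	94922	95371	1.00
347	95372	95821	1.00
348	95822	96271	1.00
349	96272	96721	1.00
350	96722	97171	1.00
351	97172	97621	1.00
352	97622	98071	1.00
353	98072	98520	1.00
354	98521	98969	1.00
355	98970	99418	1.00
356	99419	99867	1.00
357	99868	100316	1.00
358	100317	100765	1.00
359	100766	102208	1.00
360	102209	103650	1.00
361	103651	105092	1.00
362	105093	106534	1.00
363	106535	107976	1.00
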