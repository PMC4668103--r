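spot_id	fold	pattern	hybrid	stage
270	2.2	A	Xun928xZong3	D12
277	Y/N	+	Lx9801xZong3	D12
80	Y/N	+	Xun928xZong3	D8
121	Y/N	A	Lx9801xZong3	D8
148	Y/N	+	Xun928xZong3	D10
194	2.9	A	Lx9801xZong3	D10
238	3.4	++	Xun928xZong3	D12
155	Y/N	A	Xun928xZong3	D10
239	4.7	A	Xun928xZong3	D12
257	2.5	A	Xun928xZong3	D12
137	Y/N	+	Lx9801xZong3	D8
284	Y/N	A	Lx9801xZong3	D12
289	Y/N	-	Lx9801xZong3	D12
163	16.5	A	Xun928xZong3	D10
171	Y/N	A	Xun928xZong3	D10
236	4.2	++	Xun928xZong3	D12
243	6.1	+	Xun928xZong3	D12
89	Y/N	+-	Xun928xZong3	D8
118	8.4	-	Lx9801xZong3	D8
150	Y/N	A	Xun928xZong3	D10
272	Y/N	+	Xun928xZong3	D12
291	3.9	A	Lx9801xZong3	D12
79	Y/N	A	Xun928xZong3	D8
197	Y/N	-	Lx9801xZong3	D10
99	Y/N	A	Xun928xZong3	D8
117	Y/N	+	Lx9801xZong3	D8
122	Y/N	A	Lx9801xZong3	D8
123	6.8	A	Lx9801xZong3	D8
159	4.8	A	Xun928xZong3	D10
200	Y/N	A	Lx9801xZong3	D10
201	6.3	A	Lx9801xZong3	D10
212	10.1	++	Lx9801xZong3	D10
241	Y/N	A	Xun928xZong3	D12
119	Y/N	A	Lx9801xZong3	D8
152	Y/N	A	Xun928xZong3	D10
231	Y/N	A	Lx9801xZong3	D10
202	5.3	A	Lx9801xZong3	D10
76	9.2	A	Xun928xZong3	D8
138	12.9	A	Lx9801xZong3	D8
188	18.8	A	Xun928xZong3	D10
224	15.1	+	Lx9801xZong3	D10
285	Y/N	A	Lx9801xZong3	D12
96	3.6	-	Xun928xZong3	D8
255	Y/N	-	Xun928xZong3	D12
275	Y/N	+	Lx9801xZong3	D12
127	Y/N	+	Lx9801xZong3	D8
216	Y/N	+-	Lx9801xZong3	D10
298	Y/N	A	Lx9801xZong3	D12
217	Y/N	+	Lx9801xZong3	D10
223	Y/N	A	Lx9801xZong3	D10
74	Y/N	A	Xun928xZong3	D8
140	Y/N	A	Lx9801xZong3	D8
190	Y/N	A	Xun928xZong3	D10
268	Y/N	A	Xun928xZong3	D12
287	Y/N	A	Lx9801xZong3	D12
104	Y/N	A	Xun928xZong3	D8
176	Y/N	A	Xun928xZong3	D10
211	Y/N	++	Lx9801xZong3	D10
247	Y/N	A	Xun928xZong3	D12
177	Y/N	A	Xun928xZong3	D10
232	Y/N	+	Lx9801xZong3	D10
173	Y/N	A	Xun928xZong3	D10
95	Y/N	A	Xun928xZong3	D8
149	4.0	+	Xun928xZong3	D10
105	Y/N	A	Xun928xZong3	D8
160	5.1	A	Xun928xZong3	D10
165	5.2	A	Xun928xZong3	D10
204	Y/N	+	Lx9801xZong3	D10
292	Y/N	+	Lx9801xZong3	D12
86	Y/N	A	Xun928xZong3	D8
120	Y/N	A	Lx9801xZong3	D8
151	Y/N	A	Xun928xZong3	D10
220	3.8	A	Lx9801xZong3	D10
262	4.5	A	Xun928xZong3	D12
283	Y/N	+-	Lx9801xZong3	D12
164	Y/N	+	Xun928xZong3	D10
207	Y/N	+	Lx9801xZong3	D10
246	5.0	A	Xun928xZong3	D12
98	Y/N	A	Xun928xZong3	D8
244	Y/N	A	Xun928xZong3	D12
111	4.8	+-	Xun928xZong3	D8
115	Y/N	A	Xun928xZong3	D8
213	Y/N	A	Lx9801xZong3	D10
214	Y/N	A	Lx9801xZong3	D10
248	3.6	-	Xun928xZong3	D12
183	Y/N	A	Xun928xZong3	D10
110	Y/N	A	Xun928xZong3	D8
147	Y/N	-	Xun928xZong3	D10
87	Y/N	A	Xun928xZong3	D8
235	Y/N	A	Xun928xZong3	D12
88	Y/N	A	Xun928xZong3	D8
237	Y/N	+	Xun928xZong3	D12
199	5.8	-	Lx9801xZong3	D10
145	2.8	-	Xun928xZong3	D10
182	2.2	-	Xun928xZong3	D10
71	Y/N	A	Xun928xZong3	D8
124	Y/N	-	Lx9801xZong3	D8
67	3.0	A	Xun928xZong3	D8
106	Y/N	+	Xun928xZong3	D8
178	7.4	A	Xun928xZong3	D10
91	2.7	A	Xun928xZong3	D8
94	4.3	A	Xun928xZong3	D8
161	Y/N	A	Xun928xZong3	D10
72	Y/N	A	Xun928xZong3	D8
146	Y/N	A	Xun928xZong3	D10
112	3.4	A	Xun928xZong3	D8
251	Y/N	A	Xun928xZong3	D12
70	Y/N	A	Xun928xZong3	D8
258	Y/N	A	Xun928xZong3	D12
260	Y/N	A	Xun928xZong3	D12
279	Y/N	A	Lx9801xZong3	D12
252	3.4	A	Xun928xZong3	D12
229	Y/N	A	Lx9801xZong3	D10
288	Y/N	-	Lx9801xZong3	D12
267	Y/N	--	Xun928xZong3	D12
290	Y/N	++	Lx9801xZong3	D12
90	3.8	A	Xun928xZong3	D8
198	Y/N	-	Lx9801xZong3	D10
281	Y/N	+-	Lx9801xZong3	D12
225	Y/N	+	Lx9801xZong3	D10
266	Y/N	+-	Xun928xZong3	D12
286	Y/N	+	Lx9801xZong3	D12
107	2.9	A	Xun928xZong3	D8
274	Y/N	+-	Lx9801xZong3	D12
168	4.0	A	Xun928xZong3	D10
299	Y/N	-	Lx9801xZong3	D12
193	2.4	-	Xun928xZong3	D10
263	Y/N	-	Xun928xZong3	D12
69	Y/N	A	Xun928xZong3	D8
254	Y/N	A	Xun928xZong3	D12
187	2.8	+	Xun928xZong3	D10
265	11.2	A	Xun928xZong3	D12
109	Y/N	A	Xun928xZong3	D8
126	Y/N	A	Lx9801xZong3	D8
128	5.4	A	Lx9801xZong3	D8
169	4.6	+	Xun928xZong3	D10
113	Y/N	A	Xun928xZong3	D8
114	Y/N	A	Xun928xZong3	D8
135	Y/N	A	Lx9801xZong3	D8
179	Y/N	+	Xun928xZong3	D10
180	Y/N	A	Xun928xZong3	D10
245	Y/N	A	Xun928xZong3	D12
108	4.0	A	Xun928xZong3	D8
81	Y/N	A	Xun928xZong3	D8
233	Y/N	A	Xun928xZong3	D12
189	Y/N	-	Xun928xZong3	D10
116	Y/N	A	Lx9801xZong3	D8
228	Y/N	A	Lx9801xZong3	D10
210	5.4	++	Lx9801xZong3	D10
219	Y/N	A	Lx9801xZong3	D10
221	Y/N	A	Lx9801xZong3	D10
282	Y/N	A	Lx9801xZong3	D12
157	7.3	A	Xun928xZong3	D10
174	Y/N	A	Xun928xZong3	D10
259	Y/N	A	Xun928xZong3	D12
278	Y/N	+	Lx9801xZong3	D12
166	3.8	++	Xun928xZong3	D10
186	Y/N	A	Xun928xZong3	D10
218	3.5	-	Lx9801xZong3	D10
73	Y/N	+-	Xun928xZong3	D8
75	3.5	+-	Xun928xZong3	D8
141	Y/N	A	Lx9801xZong3	D8
191	Y/N	A	Xun928xZong3	D10
226	Y/N	+	Lx9801xZong3	D10
280	Y/N	A	Lx9801xZong3	D12
139	Y/N	-	Lx9801xZong3	D8
132	Y/N	A	Lx9801xZong3	D8
103	Y/N	-	Xun928xZong3	D8
130	Y/N	-	Lx9801xZong3	D8
172	Y/N	-	Xun928xZong3	D10
234	Y/N	-	Xun928xZong3	D12
129	Y/N	A	Lx9801xZong3	D8
134	Y/N	A	Lx9801xZong3	D8
209	Y/N	+	Lx9801xZong3	D10
261	3.5	--	Xun928xZong3	D12
185	Y/N	A	Xun928xZong3	D10
153	2.4	+	Xun928xZong3	D10
85	Y/N	A	Xun928xZong3	D8
264	Y/N	+-	Xun928xZong3	D12
203	Y/N	-	Lx9801xZong3	D10
293	Y/N	-	Lx9801xZong3	D12
192	Y/N	-	Xun928xZong3	D10
215	Y/N	++	Lx9801xZong3	D10
68	Y/N	A	Xun928xZong3	D8
136	Y/N	A	Lx9801xZong3	D8
181	Y/N	A	Xun928xZong3	D10
256	Y/N	A	Xun928xZong3	D12
276	Y/N	+	Lx9801xZong3	D12
167	2.6	+	Xun928xZong3	D10
97	Y/N	+	Xun928xZong3	D8
125	Y/N	+	Lx9801xZong3	D8
205	5.8	A	Lx9801xZong3	D10
250	Y/N	-	Xun928xZong3	D12
206	Y/N	-	Lx9801xZong3	D10
230	Y/N	+	Lx9801xZong3	D10
92	Y/N	+	Xun928xZong3	D8
271	Y/N	+-	Xun928xZong3	D12
175	Y/N	A	Xun928xZong3	D10
142	4.3	+	Xun928xZong3	D10
143	4.9	+	Xun928xZong3	D10
170	Y/N	+	Xun928xZong3	D10
208	Y/N	+	Lx9801xZong3	D10
249	Y/N	A	Xun928xZong3	D12
82	Y/N	A	Xun928xZong3	D8
83	9.5	A	Xun928xZong3	D8
84	Y/N	+	Xun928xZong3	D8
154	Y/N	A	Xun928xZong3	D10
195	Y/N	-	Lx9801xZong3	D10
294	Y/N	-	Lx9801xZong3	D12
196	Y/N	-	Lx9801xZong3	D10
295	Y/N	-	Lx9801xZong3	D12
77	Y/N	A	Xun928xZong3	D8
78	Y/N	A	Xun928xZong3	D8
253	3.9	--	Xun928xZong3	D12
93	Y/N	A	Xun928xZong3	D8
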