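prime	name
2	1 min to 24 h with severe intensity
3	1 to 14 days per month
5	1 to 600 s
7	15 min up to 4 h after waking
11	15 to 180 min
13	1–6 cm in diameter
17	2 to 30 min
19	30 min to 7 days in duration
23	4 to 72 h
29	Abrupt explosive intensity just before or with orgasm
31	Aggravated by physical activity
37	At least one aura symptom is positive
41	At least one aura symptom is unilateral
43	At least one aura symptom spreads gradually over 5 min
47	Between 1 s to 2 h
53	Bilateral location
59	Brainstem aura
61	Brought on by cold stimuli
67	Brought on by exercise
71	Brought on by sex
73	Brought on within 1 h of compression
79	Brought on within 1 h of traction
83	Clearly remembered onset
89	Conjunctival injection
97	Constant
101	Developing only during sleep and causing wakening
103	Each individual aura symptom lasts 5–60 min
107	Every other day to 8 per day
109	Eyelid edema
113	Fixed in size and shape
127	Forehead and facial sweating
131	Fully reversible
137	Greater than 1 per day
139	Greater than 15 days per month
149	Greater than 2 episodes
151	Greater than 20 episodes
157	Greater than 5 episodes
163	Greater than 5 min
167	Greater than 5 per day
173	Greater than 8 days per month
179	Hours to days
181	Increasing in intensity with increasing sexual excitement
191	Indomethacin responsive
193	Irregular frequency
197	Lacrimation
199	Less than 12 days per year
211	Less than 48 h
223	Max within 1 min
227	Maximal at site of compression
229	Maximal at site of traction
233	Mild to moderate pain
239	Miosis
241	Moderate to severe
251	More than 1 episode per day
257	More than 10 episodes
263	More than 3 months
269	More than 10 days per month
271	Motor aura
277	Nasal congestion
281	Nausea/vomiting
283	No conjunctival injection
293	No eyelid edema
307	No forehead and facial sweating
311	No lacrimation
313	No miosis
317	No nasal congestion
331	No nausea/vomiting
337	No orbital or supraorbital or temporal pain
347	No phonophobia
349	No photophobia
353	No ptosis
359	No restless
367	No rhinorrhea
373	Nonpulsating
379	Not aggrevated by activity
383	Orbital or supraorbital or temporal pain
389	Phonophobia
397	Photophobia
401	Provoke by cough
409	Provoke by valsalva
419	Ptosis
421	Pulsating
431	Relieve by triptan or ergot
433	Resolve within 1 h after removal of compression
439	Resolve within 1 h after removal of traction
443	Resolve within 30 min after removal of cold
449	Restless
457	Retinal aura
461	Rhinorrhea
463	Round or elliptical
467	Sensory aura
479	Severe
487	Sharply contoured
491	Single or series of stabs
499	Speech and/or language aura
503	Sudden
509	The aura is accompanied or followed within 60 min by headache
521	Two or more aura symptoms occur in succession
523	Unilateral
541	Unremitting within 24 h
547	Up to 72 h with mild intensity
557	Up to few seconds
563	Visual aura
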