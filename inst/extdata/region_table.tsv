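id	name	sensorimotor
1	primary motor cortex	TRUE
2	secondary motor cortex	TRUE
3	caudate putamen	TRUE
4	thalamus	TRUE
5	globus pallidus	TRUE
6	S1 forelimb region	TRUE
7	S1 oral dysgranular zone	TRUE
8	S1 upper lip region	TRUE
9	S1 shoulder region	TRUE
10	S1 hindlimb region	TRUE
11	S1 trunk region	TRUE
12	S1 jaw region	TRUE
13	S1 dysgranular zone	TRUE
14	S1 barrel field	TRUE
15	S1 not otherwise specified	TRUE
16	secondary somatosensory cortex	TRUE
17	hippocampus	FALSE
18	piriform cortex	FALSE
19	prelimbic cortex	FALSE
20	primary auditory cortex	FALSE
21	secondary auditory cortex dorsal	FALSE
22	secondary auditory cortex ventral	FALSE
23	cingulate cortex	FALSE
24	retrosplenial cortex	FALSE
25	primary visual cortex	FALSE
26	secondary visual cortex	FALSE
27	entorhinal cortex	FALSE
28	insular cortex	FALSE
29	orbitofrontal cortex	FALSE
30	amygdala	FALSE
31	hypothalamus	FALSE
32	septum	FALSE
33	nucleus accumbens	FALSE
34	olfactory tubercle	FALSE
35	superior colliculus	FALSE
36	inferior colliculus	FALSE
37	periaqueductal gray	FALSE
38	substantia nigra	FALSE
39	ventral tegmental area	FALSE
40	zona incerta	FALSE
41	habenula	FALSE
42	claustrum	FALSE
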