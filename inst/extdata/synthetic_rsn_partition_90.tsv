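roi_index	roi_name	network
1	ROI001	DMN
2	ROI002	DMN
3	ROI003	DMN
4	ROI004	DMN
5	ROI005	DMN
6	ROI006	DMN
7	ROI007	DMN
8	ROI008	DMN
9	ROI009	DMN
10	ROI010	DMN
11	ROI011	DMN
12	ROI012	DMN
13	ROI013	DMN
14	ROI014	DMN
15	ROI015	DMN
16	ROI016	DMN
17	ROI017	DMN
18	ROI018	DMN
19	ROI019	DMN
20	ROI020	DMN
21	ROI021	DMN
22	ROI022	DMN
23	ROI023	ATT
24	ROI024	ATT
25	ROI025	ATT
26	ROI026	ATT
27	ROI027	ATT
28	ROI028	ATT
29	ROI029	ATT
30	ROI030	ATT
31	ROI031	ATT
32	ROI032	ATT
33	ROI033	ATT
34	ROI034	ATT
35	ROI035	ATT
36	ROI036	ATT
37	ROI037	SUB
38	ROI038	SUB
39	ROI039	SUB
40	ROI040	SUB
41	ROI041	SUB
42	ROI042	SUB
43	ROI043	SUB
44	ROI044	SUB
45	ROI045	SUB
46	ROI046	SUB
47	ROI047	SUB
48	ROI048	SUB
49	ROI049	AUD
50	ROI050	AUD
51	ROI051	AUD
52	ROI052	AUD
53	ROI053	AUD
54	ROI054	AUD
55	ROI055	AUD
56	ROI056	AUD
57	ROI057	VIS
58	ROI058	VIS
59	ROI059	VIS
60	ROI060	VIS
61	ROI061	VIS
62	ROI062	VIS
63	ROI063	VIS
64	ROI064	VIS
65	ROI065	VIS
66	ROI066	VIS
67	ROI067	VIS
68	ROI068	VIS
69	ROI069	VIS
70	ROI070	VIS
71	ROI071	SEN
72	ROI072	SEN
73	ROI073	SEN
74	ROI074	SEN
75	ROI075	SEN
76	ROI076	SEN
77	ROI077	SEN
78	ROI078	SEN
79	ROI079	SEN
80	ROI080	SEN
81	ROI081	SEN
82	ROI082	SEN
83	ROI083	SEN
84	ROI084	SEN
85	ROI085	SEN
86	ROI086	SEN
87	ROI087	SEN
88	ROI088	SEN
89	ROI089	SEN
90	ROI090	SEN
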