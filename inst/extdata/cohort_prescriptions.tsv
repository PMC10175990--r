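subject_id	parcel_id	protocol
1	L_8Av	iTBS
1	R_43	cTBS
2	L_PGs	cTBS
2	L_8Av	cTBS
3	L_PGs	cTBS
3	R_PFm	iTBS
4	L_8Av	cTBS
4	L_PGs	cTBS
5	L_8Av	cTBS
5	L_PGs	iTBS
6	L_46	iTBS
6	R_46	iTBS
7	L_8Av	cTBS
7	L_PFm	cTBS
8	L_8Av	cTBS
8	L_PFm	cTBS
8	L_46	cTBS
9	R_s6-8	cTBS
9	L_8Av	cTBS
10	R_s6-8	cTBS
10	L_PGs	cTBS
11	L_8Av	cTBS
11	L_PGs	cTBS
11	R_TE1m	cTBS
12	L_8Av	cTBS
12	L_PGs	cTBS
13	L_8Av	cTBS
13	R_TE1m	iTBS
14	L_8Av	cTBS
14	R_TE1m	iTBS
15	L_46	cTBS
15	L_8Av	cTBS
16	R_s6-8	cTBS
16	L_PFm	cTBS
16	L_PGs	cTBS
17	L_8Av	cTBS
17	L_PGs	cTBS
18	L_8Av	cTBS
18	L_PGs	cTBS
19	L_8Av	cTBS
19	L_PGs	cTBS
19	L_PFm	cTBS
20	L_8Av	cTBS
20	L_6ma	cTBS
21	L_8Av	cTBS
21	L_PGs	cTBS
22	L_8Av	cTBS
22	L_PGs	cTBS
23	L_8Av	cTBS
23	L_PGs	iTBS
24	L_8Av	iTBS
24	R_PGs	cTBS
25	L_8Av	iTBS
25	L_PGs	cTBS
26	L_8Av	cTBS
26	L_PGs	cTBS
26	R_8Av	cTBS
27	L_8Av	iTBS
27	L_PGs	iTBS
28	L_8Av	cTBS
28	L_PGs	iTBS
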