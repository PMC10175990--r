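subject_id	age	gender	pre	post	week1	month1
1	57	male	15	12	3	2
2	21	male	10	5	4	4
3	29	female	21	21	18	19
4	32	male	8	3	NA	NA
5	18	female	19	12	NA	NA
6	44	male	2	2	0	0
7	51	male	17	8	6	NA
8	31	male	2	6	NA	NA
9	49	male	3	4	NA	5
10	23	female	9	8	4	2
11	18	male	12	13	NA	NA
12	46	female	21	3	NA	6
13	30	female	7	2	NA	3
14	66	male	4	5	NA	NA
15	49	male	11	6	2	2
16	31	male	1	2	NA	NA
17	34	male	0	6	1	0
18	55	male	15	14	9	NA
19	20	male	10	15	12	5
20	18	female	18	12	6	NA
21	20	male	9	10	NA	NA
22	39	male	12	5	7	5
23	71	female	8	5	NA	13
24	38	male	20	1	NA	NA
25	49	female	17	4	NA	NA
26	43	female	21	21	NA	NA
27	40	male	19	4	NA	NA
28	48	female	8	3	NA	NA
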