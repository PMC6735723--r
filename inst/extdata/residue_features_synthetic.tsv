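gene_id	residue_index	rsa	ss	disorder_p	codon_index	active_site
g00001	0	0.3711	sheet	0.1127	0	FALSE
g00001	1	0.7418	helix	0.8686	1	FALSE
g00001	2	0.1807	helix	0.7807	2	FALSE
g00001	3	0.2999	helix	0.5825	3	FALSE
g00001	4	0.115	helix	0.4942	4	FALSE
g00001	5	0.2256	helix	0.2205	5	FALSE
g00001	6	0.4371	helix	0.6431	6	FALSE
g00001	7	0.2628	helix	0.0511	7	FALSE
g00001	8	0.3876	helix	0.9055	8	FALSE
g00001	9	0	helix	0.3538	9	FALSE
g00001	10	0.2268	helix	0.3318	10	FALSE
g00001	11	0.8258	helix	0.7587	11	FALSE
g00001	12	0.2383	helix	0.3812	12	FALSE
g00001	13	0.02	helix	0.4898	13	FALSE
g00001	14	0.8606	helix	0.3908	14	FALSE
g00001	15	0.2696	helix	0.0011	15	FALSE
g00001	16	0	helix	0.8444	16	FALSE
g00001	17	0.3773	helix	0.0612	17	FALSE
g00001	18	0.2756	helix	0.5877	18	FALSE
g00001	19	0.3559	helix	0.525	19	FALSE
g00001	20	0.1055	helix	0.643	20	FALSE
g00001	21	0.2288	helix	0.7872	21	FALSE
g00001	22	0.0878	helix	0.0142	22	FALSE
g00001	23	0.4622	helix	0.9813	23	FALSE
g00001	24	0.2134	loop	0.0091	24	FALSE
g00001	25	0.2256	loop	0.6994	25	FALSE
g00001	26	0.4004	sheet	0.1539	26	FALSE
g00001	27	0.0419	loop	0.2484	27	FALSE
g00001	28	0.041	loop	0.4341	28	FALSE
g00001	29	0.1038	loop	0.1088	29	FALSE
g00001	30	0.5056	loop	0.6263	30	FALSE
g00001	31	0	loop	0.0259	31	FALSE
g00001	32	0	helix	0.017	32	FALSE
g00001	33	0.4484	helix	0.0958	33	FALSE
g00001	34	0.4629	helix	0.4023	34	FALSE
g00001	35	0.3182	helix	0.2208	35	FALSE
g00001	36	0.1444	helix	0.4001	36	FALSE
g00001	37	0.6376	loop	0.8247	37	FALSE
g00001	38	0.3554	loop	0.8635	38	FALSE
g00001	39	0.1517	loop	0.3146	39	FALSE
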