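gene_id	length_codons	intron_count	recomb_rate	expr_mean	expr_breadth	ppi_degree	chaperone_binder	localization	functional_class	prop_disordered
g00001	244	3	3.177	3.949	7	6	FALSE	nuclear	class11	0.2541
g00002	443	4	2.395	1.275	8	7	TRUE	cytoplasmic	class2	0.2573
g00003	958	0	3.884	19.464	17	3	TRUE	nuclear	class7	0.239
g00004	215	0	1.465	0.478	6	17	TRUE	nuclear	class2	0.2651
g00005	383	4	2.489	12.612	14	7	TRUE	secreted	class5	0.2689
g00006	430	6	2.115	4.452	10	21	FALSE	cytoplasmic	class8	0.2442
g00007	590	2	0.796	11.073	12	12	FALSE	cytoplasmic	class12	0.2373
g00008	351	4	0.489	8.013	10	7	FALSE	endomembrane	class12	0.2678
g00009	1191	4	1.606	24.023	16	25	FALSE	mitochondrial	class11	0.2452
g00010	371	8	1.113	1.193	5	40	FALSE	mitochondrial	class11	0.2534
g00011	503	3	1.7	23.792	16	2	TRUE	cytoplasmic	class3	0.2584
g00012	686	4	4.816	29.492	16	5	FALSE	plasma_membrane	class6	0.2493
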