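#name	n	Ln	sfs_nonsyn(1..n-1)	Ls	sfs_syn(1..n-1)	Ln	Dn	Ls	Ds
fix_planted	4	25.5	0.0	1.0	0.0	9.5	1.0	0.0	0.0	25.5	1.0	9.5	1.0
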