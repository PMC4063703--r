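bait	background	prey	unique_peptides
Yth1	wt	Cft1	22
Yth1	wt	Cft2	18
Yth1	wt	Ysh1	15
Yth1	wt	Pta1	12
Yth1	wt	Pfs2	14
Yth1	wt	Ssu72	6
Yth1	wt	Swd2.2	9
Yth1	wt	Ppn1	11
Yth1	wt	Dis2	7
Yth1	wt	Hsp90	5
Yth1	wt	Act1	3
Yth1	swd2.2	Cft1	21
Yth1	swd2.2	Cft2	17
Yth1	swd2.2	Ysh1	16
Yth1	swd2.2	Pta1	11
Yth1	swd2.2	Pfs2	14
Yth1	swd2.2	Ssu72	7
Yth1	swd2.2	Hsp90	4
Yth1	swd2.2	Act1	2
Yth1	ppn1	Cft1	20
Yth1	ppn1	Cft2	19
Yth1	ppn1	Ysh1	14
Yth1	ppn1	Pta1	13
Yth1	ppn1	Pfs2	15
Yth1	ppn1	Ssu72	6
Yth1	ppn1	Hsp90	6
Yth1	ppn1	Act1	3
Yth1	dis2	Cft1	22
Yth1	dis2	Cft2	18
Yth1	dis2	Ysh1	15
Yth1	dis2	Pta1	12
Yth1	dis2	Pfs2	13
Yth1	dis2	Ssu72	6
Yth1	dis2	Hsp90	5
Yth1	dis2	Act1	4
no_tag	wt	Hsp90	8
no_tag	wt	Act1	5
no_tag	wt	Rpl3	4
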