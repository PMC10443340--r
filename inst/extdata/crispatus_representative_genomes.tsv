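assembly_id	strain	genome_size_mbp	cds	completeness_pct	isolation_source
GCF_000162255.1	125-2-CHN	2.30525	2032	99.03	Human vagina
GCF_000162315.1	MV-3A-US	2.43708	2252	98.38	Human vagina
GCF_002861805.1	UMB0824	2.17405	2061	99.03	Human urine
GCF_002861815.1	UMB0085	2.17506	2081	99.03	Human urine
GCF_009857395.1	Indica2	2.20949	2028	99.03	Human vagina
GCF_007713895.1	NCK1350	2.04734	1932	99.03	Human stool
GCF_013456995.1	B4	2.03959	1902	99.03	Human stool
GCF_000160515.1	JV-V01	2.2172	1992	98.03	Human vagina
GCF_014654865.1	BC5	2.06419	1901	99.03	Human vagina
GCF_015669875.1	D31t1	2.2782	2120	99.03	Human stool
GCF_018987235.1	ATCC 33820	2.23909	2020	99.03	Human saliva
GCF_020042005.1	Lc1700	2.81896	2632	98.86	Human vagina
GCF_021278925.1	lc83	2.30843	2112	98.9	Human vagina
GCF_025194085.1	CIRM-BIA 2111	2.00737	1865	99.03	Human stool
GCF_025194045.1	CIRM-BIA 2233	2.24513	2127	99.03	Human vagina
new_seq	LMG11440	2.032412	2087	98.86	Human vagina
new_seq	LMG12005	2.019682	2014	98.94	Human vagina
new_seq	LMG18189	2.094399	2079	99.03	Human saliva
new_seq	LMG11415	2.030901	2004	99.03	Human saliva
new_seq	LMG18200	2.208098	2182	99.03	Human stool
new_seq	LB93	2.202822	2340	99.03	Human vagina
new_seq	LB97	2.263389	2422	99.03	Human vagina
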