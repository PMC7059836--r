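contig	fn	VQSRTrancheSNP99.50to99.90	VQSRTrancheSNP99.90to100.00
chr1	5224	3666	138
chr2	5071	3476	75
chr3	4635	3198	92
chr4	4592	3274	98
chr5	3949	2808	66
chr6	4916	3489	123
chr7	3462	2338	78
chr8	3246	2155	65
chr9	2652	1750	42
chr10	2893	1870	64
chr11	3896	2768	91
chr12	2802	1937	69
chr13	2024	1261	32
chr14	2177	1463	48
chr15	1643	1028	33
chr16	977	528	17
chr17	1359	835	37
chr18	1261	821	25
chr19	1401	929	38
chr20	1051	623	18
chr21	728	477	10
chr22	628	477	10
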