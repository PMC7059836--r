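class	contig	this_work	lift_over	p3
snv	chr1	0.99	1.15	2.42
snv	chr2	0.53	0.70	0.70
snv	chr3	0.48	0.77	0.72
snv	chr4	0.50	0.66	2.45
snv	chr5	0.51	0.68	2.30
snv	chr6	1.40	1.59	2.35
snv	chr7	0.74	0.93	1.23
snv	chr8	0.61	0.85	2.16
snv	chr9	0.43	0.70	2.36
snv	chr10	0.89	1.17	1.49
snv	chr11	0.57	0.65	2.50
snv	chr12	0.44	0.63	0.65
snv	chr13	0.44	0.64	0.66
snv	chr14	0.44	0.69	0.68
snv	chr15	0.61	0.77	0.77
snv	chr16	1.17	1.35	0.60
snv	chr17	1.62	1.77	0.82
snv	chr18	0.53	0.74	2.38
snv	chr19	0.37	0.67	2.94
snv	chr20	0.46	0.66	0.59
snv	chr21	0.44	0.58	0.57
snv	chr22	1.52	1.73	2.53
indel	chr1	2.55	4.85	9.32
indel	chr2	0.66	1.29	1.32
indel	chr3	0.44	1.25	1.23
indel	chr4	0.56	0.93	7.64
indel	chr5	0.57	1.16	8.35
indel	chr6	4.67	7.10	8.22
indel	chr7	2.26	3.26	3.68
indel	chr8	0.95	2.34	8.70
indel	chr9	0.40	1.51	8.67
indel	chr10	2.91	4.55	5.17
indel	chr11	0.71	0.99	8.68
indel	chr12	0.43	1.12	1.26
indel	chr13	0.52	0.89	0.73
indel	chr14	0.51	1.18	1.13
indel	chr15	0.58	1.12	1.17
indel	chr16	5.56	9.14	1.10
indel	chr17	6.35	10.74	1.53
indel	chr18	0.56	1.24	8.97
indel	chr19	0.62	2.01	12.75
indel	chr20	0.86	1.65	1.47
indel	chr21	0.73	1.15	1.24
indel	chr22	5.83	10.04	11.57
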