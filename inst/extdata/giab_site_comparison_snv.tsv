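contig	tp	fn	fp
chr1	238323	8965	1347
chr2	237017	8791	1264
chr3	214201	8520	1134
chr4	188608	7860	847
chr5	181015	7031	865
chr6	197830	8151	940
chr7	166888	5982	854
chr8	145748	5700	678
chr9	131987	4899	635
chr10	153504	5480	815
chr11	154516	6720	775
chr12	136457	5008	745
chr13	121294	3889	560
chr14	99613	4122	493
chr15	85881	3031	386
chr16	54542	1850	282
chr17	73765	2524	484
chr18	73419	2360	344
chr19	56210	2788	461
chr20	64786	2154	419
chr21	42453	1329	225
chr22	33351	1099	193
chrX	109	7	2
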