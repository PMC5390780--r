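# Published per-gene 3'-end category percentages from a targeted pre-tRNA
# sequencing study of budding yeast (wild type, a Maf1 deletion strain and a
# Rex1 deletion strain, each grown in glucose at 30C or shifted to glycerol
# at 37C). Percentages are of all reads aligned to the given pre-tRNA in the
# library; categories as in the package (oligo_a = >=1 extra 3' adenosine,
# plus_c/plus_cc/plus_cca = partial or full CCA at the gene end,
# processed_exact = end-processed with nothing added). Input data for
# fig2-from-table / endProcessedShares().
gene_id	library_id	total_reads	oligo_a	plus_c	plus_cc	plus_cca	processed_exact
tI(UAU)	wt_YPD30	135474	14.3	2.7	5.2	12.1	0.0
tI(UAU)	wt_YPGly37	340814	13.4	10.2	15.1	9.5	0.1
tI(UAU)	maf1d_YPD30	98916	13.9	1.6	6.3	19.8	0.0
tI(UAU)	maf1d_YPGly37	115786	22.6	9.9	7.2	3.0	0.1
tI(UAU)	rex1d_YPD30	182691	19.4	1.1	1.0	6.2	0.0
tI(UAU)	rex1d_YPGly37	748459	16.3	1.9	0.9	4.9	0.0
tF(GAA)	wt_YPD30	48710	10.9	1.2	3.3	2.5	0.9
tF(GAA)	wt_YPGly37	17533	8.6	2.4	8.5	3.9	1.3
tF(GAA)	maf1d_YPD30	38622	6.6	1.4	2.9	3.9	0.8
tF(GAA)	maf1d_YPGly37	83422	5.4	1.2	8.6	2.4	0.7
tF(GAA)	rex1d_YPD30	94244	7.7	6.4	5.0	2.2	0.5
tF(GAA)	rex1d_YPGly37	38118	12.8	0.9	1.8	6.2	0.4
tK(UUU)	wt_YPD30	578382	7.9	0.8	1.1	44.0	0.1
tK(UUU)	wt_YPGly37	348689	20.8	1.9	4.3	3.3	0.9
tK(UUU)	maf1d_YPD30	307017	13.7	1.5	1.2	1.8	0.4
tK(UUU)	maf1d_YPGly37	321958	27.7	4.0	1.4	1.7	10.1
tK(UUU)	rex1d_YPD30	427862	11.0	0.5	0.2	1.2	0.2
tK(UUU)	rex1d_YPGly37	458097	8.9	3.2	1.5	3.5	0.6
tL(CAA)	wt_YPD30	2339638	2.4	1.9	33.9	29.4	0.4
tL(CAA)	wt_YPGly37	2450426	4.1	5.6	12.0	51.4	0.4
tL(CAA)	maf1d_YPD30	517398	3.5	1.4	10.6	55.4	0.3
tL(CAA)	maf1d_YPGly37	1946043	7.7	7.6	36.9	12.9	0.6
tL(CAA)	rex1d_YPD30	669469	8.3	2.0	0.6	62.0	0.7
tL(CAA)	rex1d_YPGly37	406151	16.7	3.3	2.4	33.3	1.0
tW(CCA)	wt_YPD30	622499	10.2	0.4	1.8	17.0	0.7
tW(CCA)	wt_YPGly37	2033185	18.1	0.3	1.1	12.6	0.2
tW(CCA)	maf1d_YPD30	450514	6.1	0.7	6.4	25.7	0.2
tW(CCA)	maf1d_YPGly37	858116	28.6	5.6	2.9	4.5	0.9
tW(CCA)	rex1d_YPD30	486535	15.0	0.9	0.3	26.0	0.6
tW(CCA)	rex1d_YPGly37	1070615	26.7	2.4	1.1	25.1	1.4
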