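class	cell_type	n_cells
Class 1	mBrain B lymphocytes	1311
Class 2	mBrain Endothelial cells	159
Class 3	mBrain Epithelial cells	15463
Class 4	mBrain Fibroblasts	444
Class 5	mBrain MAST cells	508
Class 6	mBrain Myeloid cells	5657
Class 7	mBrain T/NK cells	2683
Class 8	mLN B lymphocytes	6062
Class 9	mLN Epithelial cells	3053
Class 10	mLN Myeloid cells	5442
Class 11	mLN T/NK cells	5069
Class 12	nLN B lymphocytes	10584
Class 13	nLN Myeloid cells	1288
Class 14	nLN T/NK cells	19478
Class 15	nLung B lymphocytes	634
Class 16	nLung Endothelial cells	1295
Class 17	nLung Epithelial cells	3703
Class 18	nLung Fibroblasts	1585
Class 19	nLung MAST cells	1079
Class 20	nLung Myeloid cells	16672
Class 21	nLung T/NK cells	11413
Class 22	PE B lymphocytes	3285
Class 23	PE Epithelial cells	396
Class 24	PE Myeloid cells	3063
Class 25	PE T/NK cells	9192
Class 26	tLung B lymphocytes	5781
Class 27	tLung Endothelial cells	645
Class 28	tLung Epithelial cells	13852
Class 29	tLung Fibroblasts	1739
Class 30	tLung MAST cells	1809
Class 31	tLung Myeloid cells	10123
Class 32	tLung T/NK cells	16568
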