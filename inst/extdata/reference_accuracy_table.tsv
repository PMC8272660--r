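testing_object	pso_ls_twin_svm	lda	bp	pnn
1	88.19	87.24	72.43	83.45
2	64.35	57.32	62.34	61.35
3	93.42	91.34	97.53	88.24
4	65.34	63.24	71.34	70.12
5	76.35	54.87	52.34	50.35
6	67.34	70.23	74.45	65.24
7	75.23	70.43	74.14	58.33
8	88.89	83.25	87.24	91.34
9	78.34	73.42	76.35	73.24
10	67.24	70.78	66.24	70.43
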