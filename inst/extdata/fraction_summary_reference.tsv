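statistic	AF1	AF13	AF35	AFPPH	TF13	TF35	TFPPH
peptide_ids	3968	5535	5872	6032	5241	6085	6325
mean_length	6.36	7.75	8.67	8.76	8.17	9.66	9.79
weighted_mean_length	4.80	6.57	7.77	7.79	7.91	9.50	9.51
mean_charge	-0.41	-0.68	-0.82	-0.82	-0.72	-1.01	-1.02
weighted_mean_charge	-0.30	-0.64	-0.83	-0.78	-0.64	-0.98	-1.02
Ala	4.2	3.7	4.0	3.8	4.1	5.0	4.8
Arg	0.7	1.4	1.6	1.5	1.6	1.9	1.6
Asn	2.1	3.5	3.8	3.8	4.2	4.5	4.4
Asp	4.0	7.6	8.4	7.8	5.5	8.0	7.9
Cys	0.2	0.3	0.3	0.6	0.1	0.3	0.4
Gln	1.4	1.9	2.0	2.1	1.3	1.6	1.5
Glu	2.7	4.6	5.8	5.5	5.8	6.6	6.9
Gly	8.2	9.6	9.9	9.7	11.3	12.4	11.2
His	0.6	0.7	0.6	0.7	0.7	0.6	0.6
Ile	1.3	3.0	4.2	3.8	4.2	4.9	4.9
Leu	23.5	18.3	15.4	15.4	15.1	11.3	11.3
Lys	0.7	1.4	2.1	2.4	1.7	2.5	2.7
Met	0.8	1.0	0.9	0.8	1.1	0.9	1.2
Phe	12.8	7.8	6.4	6.4	6.5	4.2	4.6
Pro	14.2	12.4	11.9	12.1	12.9	10.6	11.0
Ser	2.9	3.4	3.8	4.6	4.8	5.7	5.8
Thr	3.3	4.6	5.3	5.4	5.5	6.7	6.4
Trp	3.3	1.6	1.1	1.3	1.1	0.7	0.7
Tyr	3.6	3.7	3.0	3.3	2.7	2.7	2.8
Val	9.4	9.6	9.4	8.8	9.8	9.2	9.3
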