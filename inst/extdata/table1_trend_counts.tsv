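# Binned withdrawal/precaution counts across ten equal-width population-score
# (AUC) bins, with the per-bin study-drug totals in the final row.
row	~0.1	~0.2	~0.3	~0.4	~0.5	~0.6	~0.7	~0.8	~0.9	~1.0
Total withdrawn	1	4	7	13	30	34	39	16	6	4
UN or EMA	1	3	7	11	26	31	34	15	4	2
UN or DrugBank	1	3	5	5	25	26	28	12	5	3
EMA or DrugBank	1	4	3	11	16	14	26	8	5	3
UN	1	2	5	3	21	23	23	11	3	1
EMA	0	1	2	8	6	8	12	4	1	1
DrugBank	1	3	1	3	10	6	14	4	4	2
Beers criteria	0	1	6	7	16	25	25	6	3	1
FDA pharmacogenomics	0	0	6	11	17	32	19	7	3	1
Total study drugs	5	14	34	68	144	217	234	167	88	70
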