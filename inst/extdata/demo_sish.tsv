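case_id	gene	core_id	gene_signals	small_clusters	large_clusters	chr_signals
case_0008	HER2	1	6	0	0	2
case_0008	HER2	2	6	0	0	2
case_0008	HER2	1	6	0	0	2
case_0008	HER2	2	6	0	0	2
case_0008	HER2	1	6	0	0	2
case_0008	HER2	2	6	0	0	2
case_0008	HER2	1	6	0	0	2
case_0008	HER2	2	6	0	0	2
case_0008	HER2	1	6	0	0	2
case_0008	HER2	2	6	0	0	2
case_0008	HER2	1	6	0	0	2
case_0008	HER2	2	6	0	0	2
case_0008	HER2	1	6	0	0	2
case_0008	HER2	2	6	0	0	2
case_0008	HER2	1	6	0	0	2
case_0008	HER2	2	6	0	0	2
case_0008	HER2	1	6	0	0	2
case_0008	HER2	2	6	0	0	2
case_0008	HER2	1	6	0	0	2
case_0008	HER2	2	6	0	0	2
case_0008	HER2	1	6	0	0	2
case_0008	HER2	2	6	0	0	2
case_0008	HER2	1	6	0	0	2
case_0008	HER2	2	6	0	0	2
case_0008	HER2	1	6	0	0	2
case_0008	HER2	2	6	0	0	2
case_0008	HER2	1	6	0	0	2
case_0008	HER2	2	6	0	0	2
case_0008	HER2	1	6	0	0	2
case_0008	HER2	2	6	0	0	2
case_0008	HER2	1	6	0	0	2
case_0008	HER2	2	6	0	0	2
case_0008	HER2	1	6	0	0	2
case_0008	HER2	2	6	0	0	2
case_0008	HER2	1	6	0	0	2
case_0008	HER2	2	6	0	0	2
case_0008	HER2	1	6	0	0	2
case_0008	HER2	2	6	0	0	2
case_0008	HER2	1	6	0	0	2
case_0008	HER2	2	6	0	0	2
case_0008	HER2	1	6	0	0	2
case_0008	HER2	2	6	0	0	2
case_0008	HER2	1	6	0	0	2
case_0008	HER2	2	6	0	0	2
case_0008	HER2	1	6	0	0	2
case_0008	HER2	2	6	0	0	2
case_0008	HER2	1	6	0	0	2
case_0008	HER2	2	6	0	0	2
case_0008	HER2	1	6	0	0	2
case_0008	HER2	2	6	0	0	2
case_0008	HER2	1	6	0	0	2
case_0008	HER2	2	6	0	0	2
case_0008	HER2	1	6	0	0	2
case_0008	HER2	2	6	0	0	2
case_0008	HER2	1	6	0	0	2
case_0008	HER2	2	6	0	0	2
case_0008	HER2	1	6	0	0	2
case_0008	HER2	2	6	0	0	2
case_0008	HER2	1	6	0	0	2
case_0008	HER2	2	6	0	0	2
case_0009	HER2	1	6	0	0	2
case_0009	HER2	2	6	0	0	2
case_0009	HER2	1	6	0	0	2
case_0009	HER2	2	6	0	0	2
case_0009	HER2	1	6	0	0	2
case_0009	HER2	2	6	0	0	2
case_0009	HER2	1	6	0	0	2
case_0009	HER2	2	6	0	0	2
case_0009	HER2	1	6	0	0	2
case_0009	HER2	2	6	0	0	2
case_0009	HER2	1	6	0	0	2
case_0009	HER2	2	6	0	0	2
case_0009	HER2	1	6	0	0	2
case_0009	HER2	2	6	0	0	2
case_0009	HER2	1	6	0	0	2
case_0009	HER2	2	6	0	0	2
case_0009	HER2	1	6	0	0	2
case_0009	HER2	2	6	0	0	2
case_0009	HER2	1	6	0	0	2
case_0009	HER2	2	6	0	0	2
case_0009	HER2	1	6	0	0	2
case_0009	HER2	2	6	0	0	2
case_0009	HER2	1	6	0	0	2
case_0009	HER2	2	6	0	0	2
case_0009	HER2	1	6	0	0	2
case_0009	HER2	2	6	0	0	2
case_0009	HER2	1	6	0	0	2
case_0009	HER2	2	6	0	0	2
case_0009	HER2	1	6	0	0	2
case_0009	HER2	2	6	0	0	2
case_0009	HER2	1	6	0	0	2
case_0009	HER2	2	6	0	0	2
case_0009	HER2	1	6	0	0	2
case_0009	HER2	2	6	0	0	2
case_0009	HER2	1	6	0	0	2
case_0009	HER2	2	6	0	0	2
case_0009	HER2	1	6	0	0	2
case_0009	HER2	2	6	0	0	2
case_0009	HER2	1	6	0	0	2
case_0009	HER2	2	6	0	0	2
case_0009	HER2	1	6	0	0	2
case_0009	HER2	2	6	0	0	2
case_0009	HER2	1	6	0	0	2
case_0009	HER2	2	6	0	0	2
case_0009	HER2	1	6	0	0	2
case_0009	HER2	2	6	0	0	2
case_0009	HER2	1	6	0	0	2
case_0009	HER2	2	6	0	0	2
case_0009	HER2	1	6	0	0	2
case_0009	HER2	2	6	0	0	2
case_0009	HER2	1	6	0	0	2
case_0009	HER2	2	6	0	0	2
case_0009	HER2	1	6	0	0	2
case_0009	HER2	2	6	0	0	2
case_0009	HER2	1	6	0	0	2
case_0009	HER2	2	6	0	0	2
case_0009	HER2	1	6	0	0	2
case_0009	HER2	2	6	0	0	2
case_0009	HER2	1	6	0	0	2
case_0009	HER2	2	6	0	0	2
case_0010	EGFR	1	2	0	0	2
case_0010	EGFR	2	2	0	0	2
case_0010	EGFR	1	2	0	0	2
case_0010	EGFR	2	2	0	0	2
case_0010	EGFR	1	2	0	0	2
case_0010	EGFR	2	2	0	0	2
case_0010	EGFR	1	2	0	0	2
case_0010	EGFR	2	2	0	0	2
case_0010	EGFR	1	2	0	0	2
case_0010	EGFR	2	2	0	0	2
case_0010	EGFR	1	2	0	0	2
case_0010	EGFR	2	2	0	0	2
case_0010	EGFR	1	2	0	0	2
case_0010	EGFR	2	2	0	0	2
case_0010	EGFR	1	2	0	0	2
case_0010	EGFR	2	2	0	0	2
case_0010	EGFR	1	2	0	0	2
case_0010	EGFR	2	2	0	0	2
case_0010	EGFR	1	2	0	0	2
case_0010	EGFR	2	2	0	0	2
case_0010	EGFR	1	2	0	0	2
case_0010	EGFR	2	2	0	0	2
case_0010	EGFR	1	2	0	0	2
case_0010	EGFR	2	2	0	0	2
case_0010	EGFR	1	2	0	0	2
case_0010	EGFR	2	2	0	0	2
case_0010	EGFR	1	2	0	0	2
case_0010	EGFR	2	2	0	0	2
case_0010	EGFR	1	2	0	0	2
case_0010	EGFR	2	2	0	0	2
case_0010	EGFR	1	2	0	0	2
case_0010	EGFR	2	2	0	0	2
case_0010	EGFR	1	2	0	0	2
case_0010	EGFR	2	2	0	0	2
case_0010	EGFR	1	2	0	0	2
case_0010	EGFR	2	2	0	0	2
case_0010	EGFR	1	2	0	0	2
case_0010	EGFR	2	2	0	0	2
case_0010	EGFR	1	2	0	0	2
case_0010	EGFR	2	2	0	0	2
case_0010	EGFR	1	2	0	0	2
case_0010	EGFR	2	2	0	0	2
case_0010	EGFR	1	2	0	0	2
case_0010	EGFR	2	2	0	0	2
case_0010	EGFR	1	2	0	0	2
case_0010	EGFR	2	2	0	0	2
case_0010	EGFR	1	2	0	0	2
case_0010	EGFR	2	2	0	0	2
case_0010	EGFR	1	2	0	0	2
case_0010	EGFR	2	2	0	0	2
case_0010	EGFR	1	2	0	0	2
case_0010	EGFR	2	2	0	0	2
case_0010	EGFR	1	2	0	0	2
case_0010	EGFR	2	2	0	0	2
case_0010	EGFR	1	2	0	0	2
case_0010	EGFR	2	2	0	0	2
case_0010	EGFR	1	2	0	0	2
case_0010	EGFR	2	2	0	0	2
case_0010	EGFR	1	2	0	0	2
case_0010	EGFR	2	2	0	0	2
case_0011	EGFR	1	2	0	0	2
case_0011	EGFR	2	2	0	0	2
case_0011	EGFR	1	2	0	0	2
case_0011	EGFR	2	2	0	0	2
case_0011	EGFR	1	2	0	0	2
case_0011	EGFR	2	2	0	0	2
case_0011	EGFR	1	2	0	0	2
case_0011	EGFR	2	2	0	0	2
case_0011	EGFR	1	2	0	0	2
case_0011	EGFR	2	2	0	0	2
case_0011	EGFR	1	2	0	0	2
case_0011	EGFR	2	2	0	0	2
case_0011	EGFR	1	2	0	0	2
case_0011	EGFR	2	2	0	0	2
case_0011	EGFR	1	2	0	0	2
case_0011	EGFR	2	2	0	0	2
case_0011	EGFR	1	2	0	0	2
case_0011	EGFR	2	2	0	0	2
case_0011	EGFR	1	2	0	0	2
case_0011	EGFR	2	2	0	0	2
case_0011	EGFR	1	2	0	0	2
case_0011	EGFR	2	2	0	0	2
case_0011	EGFR	1	2	0	0	2
case_0011	EGFR	2	2	0	0	2
case_0011	EGFR	1	2	0	0	2
case_0011	EGFR	2	2	0	0	2
case_0011	EGFR	1	2	0	0	2
case_0011	EGFR	2	2	0	0	2
case_0011	EGFR	1	2	0	0	2
case_0011	EGFR	2	2	0	0	2
case_0011	EGFR	1	2	0	0	2
case_0011	EGFR	2	2	0	0	2
case_0011	EGFR	1	2	0	0	2
case_0011	EGFR	2	2	0	0	2
case_0011	EGFR	1	2	0	0	2
case_0011	EGFR	2	2	0	0	2
case_0011	EGFR	1	2	0	0	2
case_0011	EGFR	2	2	0	0	2
case_0011	EGFR	1	2	0	0	2
case_0011	EGFR	2	2	0	0	2
case_0011	EGFR	1	2	0	0	2
case_0011	EGFR	2	2	0	0	2
case_0011	EGFR	1	2	0	0	2
case_0011	EGFR	2	2	0	0	2
case_0011	EGFR	1	2	0	0	2
case_0011	EGFR	2	2	0	0	2
case_0011	EGFR	1	2	0	0	2
case_0011	EGFR	2	2	0	0	2
case_0011	EGFR	1	2	0	0	2
case_0011	EGFR	2	2	0	0	2
case_0011	EGFR	1	2	0	0	2
case_0011	EGFR	2	2	0	0	2
case_0011	EGFR	1	2	0	0	2
case_0011	EGFR	2	2	0	0	2
case_0011	EGFR	1	2	0	0	2
case_0011	EGFR	2	2	0	0	2
case_0011	EGFR	1	2	0	0	2
case_0011	EGFR	2	2	0	0	2
case_0011	EGFR	1	2	0	0	2
case_0011	EGFR	2	2	0	0	2
case_0012	EGFR	1	2	0	0	2
case_0012	EGFR	2	2	0	0	2
case_0012	EGFR	1	2	0	0	2
case_0012	EGFR	2	2	0	0	2
case_0012	EGFR	1	2	0	0	2
case_0012	EGFR	2	2	0	0	2
case_0012	EGFR	1	2	0	0	2
case_0012	EGFR	2	2	0	0	2
case_0012	EGFR	1	2	0	0	2
case_0012	EGFR	2	2	0	0	2
case_0012	EGFR	1	2	0	0	2
case_0012	EGFR	2	2	0	0	2
case_0012	EGFR	1	2	0	0	2
case_0012	EGFR	2	2	0	0	2
case_0012	EGFR	1	2	0	0	2
case_0012	EGFR	2	2	0	0	2
case_0012	EGFR	1	2	0	0	2
case_0012	EGFR	2	2	0	0	2
case_0012	EGFR	1	2	0	0	2
case_0012	EGFR	2	2	0	0	2
case_0012	EGFR	1	2	0	0	2
case_0012	EGFR	2	2	0	0	2
case_0012	EGFR	1	2	0	0	2
case_0012	EGFR	2	2	0	0	2
case_0012	EGFR	1	2	0	0	2
case_0012	EGFR	2	2	0	0	2
case_0012	EGFR	1	2	0	0	2
case_0012	EGFR	2	2	0	0	2
case_0012	EGFR	1	2	0	0	2
case_0012	EGFR	2	2	0	0	2
case_0012	EGFR	1	2	0	0	2
case_0012	EGFR	2	2	0	0	2
case_0012	EGFR	1	2	0	0	2
case_0012	EGFR	2	2	0	0	2
case_0012	EGFR	1	2	0	0	2
case_0012	EGFR	2	2	0	0	2
case_0012	EGFR	1	2	0	0	2
case_0012	EGFR	2	2	0	0	2
case_0012	EGFR	1	2	0	0	2
case_0012	EGFR	2	2	0	0	2
case_0012	EGFR	1	2	0	0	2
case_0012	EGFR	2	2	0	0	2
case_0012	EGFR	1	2	0	0	2
case_0012	EGFR	2	2	0	0	2
case_0012	EGFR	1	2	0	0	2
case_0012	EGFR	2	2	0	0	2
case_0012	EGFR	1	2	0	0	2
case_0012	EGFR	2	2	0	0	2
case_0012	EGFR	1	2	0	0	2
case_0012	EGFR	2	2	0	0	2
case_0012	EGFR	1	2	0	0	2
case_0012	EGFR	2	2	0	0	2
case_0012	EGFR	1	2	0	0	2
case_0012	EGFR	2	2	0	0	2
case_0012	EGFR	1	2	0	0	2
case_0012	EGFR	2	2	0	0	2
case_0012	EGFR	1	2	0	0	2
case_0012	EGFR	2	2	0	0	2
case_0012	EGFR	1	2	0	0	2
case_0012	EGFR	2	2	0	0	2
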