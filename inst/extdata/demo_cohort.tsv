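case_id	age	sex	location	size_cm	differentiation	lauren	lvi	lnm	pt_stage	overall_stage	egfr_ihc	her2_ihc	met_ihc	mlh1	msh2	msh6	pms2	p53_class	p53_pct	eber	rfs_months	rfs_event	os_months	os_event
case_0001	70.6	male	lower_third	7.6	undifferentiated	diffuse	present	absent	T3	IV	0	0	0	intact	intact	intact	intact	other		positive	14.9	censored	14.9	censored
case_0002	48.8	male	upper_mid_third	2.6	undifferentiated	diffuse	absent	absent	T2	III	0	0	0	intact	intact	intact	intact	other		positive	56.74	censored	56.74	censored
case_0003	78.4	female	upper_mid_third	12	undifferentiated	diffuse	present	absent	T3	IV	0	0	0	lost	intact	intact	lost	other		negative	65.09	event	86.74	censored
case_0004	39.4	female	lower_third	4.9	undifferentiated	diffuse	present	absent	T3	IV	0	0	0	lost	intact	intact	lost	other		negative	63.08	censored	63.08	censored
case_0005	50.5	male	upper_mid_third	1.1	undifferentiated	diffuse	absent	absent	T2	IV	0	0	0	intact	intact	intact	intact	other		negative	3.25	event	5.78	death
case_0006	63.2	female	lower_third	26.2	differentiated	diffuse	absent	present	T3	IV	0	0	0	intact	intact	intact	intact	other		negative	4.9	event	4.9	death
case_0007	20	male	lower_third	20.4	undifferentiated	diffuse	absent	present	T4	III	0	0	0	intact	intact	intact	intact	other		negative	12.1	event	12.1	death
case_0008	45.2	male	lower_third	7.8	undifferentiated	intestinal	absent	absent	T2	IV	0	3	0	intact	intact	intact	intact	complete_loss		negative	55.51	event	55.51	death
case_0009	50.3	female	upper_mid_third	11.6	undifferentiated	intestinal	absent	absent	T2	IV	0	3	0	intact	intact	intact	intact	complete_loss		negative	19.24	event	19.24	death
case_0010	49.2	male	lower_third	1.1	undifferentiated	intestinal	absent	present	T4	IV	2	0	0	intact	intact	intact	intact	complete_loss		negative	15.12	event	26.95	death
case_0011	55.8	male	upper_mid_third	1.9	undifferentiated	intestinal	absent	absent	T3	IV	2	0	0	intact	intact	intact	intact	complete_loss		negative	0.03	event	1.13	death
case_0012	54.2	male	upper_mid_third	8.4	undifferentiated	intestinal	present	present	T4	III	2	0	0	intact	intact	intact	intact	complete_loss		negative	28.23	event	28.23	death
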