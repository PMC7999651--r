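# schema_version: 1
# Group-level pharmacokinetic summary statistics of the reference atorvastatin
# cohort: 156 healthy volunteers from five 80 mg single-oral-dose
# bioequivalence clinical trials, stratified by demographics, trial design and
# pharmacogene genotype/phenotype. Used as calibration targets for the
# simulator and as arithmetic inputs for consistency checks.
# Parameters: auc_inf (ng*h/mL), cmax (ng/mL), auc_dw (kg*h*ng/(mL*mg)),
# cmax_dw (kg*ng/(mL*mg)), tmax (h), t_half (h), vd_f (L/kg as printed),
# cl_f (printed label L/(h*kg); magnitude corresponds to mL/(h*kg)).
# Dispersion: cv = CV% (100*SD/mean); sd = standard deviation where the source
# reported SD instead of CV%.
stratifier	level	n	parameter	mean	cv	sd
overall	Total	156	auc_inf	166.6	NA	89.1
sex	Female	85	auc_inf	183.6	NA	90.7
sex	Male	71	auc_inf	146.3	NA	83.4
overall	Total	156	cmax	39.0	NA	25.3
sex	Female	85	cmax	44.8	NA	25.5
sex	Male	71	cmax	32.0	NA	23.3
sex	Female	85	auc_dw	142.6	56.7	NA
sex	Female	85	cmax_dw	34.3	61.2	NA
sex	Female	85	tmax	1.4	57.1	NA
sex	Female	85	t_half	9.3	31.2	NA
sex	Female	85	vd_f	124.0	66.3	NA
sex	Female	85	cl_f	9023.4	49.6	NA
sex	Male	71	auc_dw	136.6	58.4	NA
sex	Male	71	cmax_dw	29.9	74.9	NA
sex	Male	71	tmax	1.4	57.1	NA
sex	Male	71	t_half	8.7	25.3	NA
sex	Male	71	vd_f	117.0	52.3	NA
sex	Male	71	cl_f	9248.5	42.7	NA
trial	A	14	auc_dw	129.2	35.9	NA
trial	A	14	cmax_dw	22.7	36.1	NA
trial	A	14	tmax	1.7	88.2	NA
trial	A	14	t_half	8.1	23.5	NA
trial	A	14	vd_f	103.5	45.1	NA
trial	A	14	cl_f	8745	35.5	NA
trial	B	30	auc_dw	174.9	63.0	NA
trial	B	30	cmax_dw	36.1	58.2	NA
trial	B	30	tmax	1.5	53.3	NA
trial	B	30	t_half	9.1	23.1	NA
trial	B	30	vd_f	107.3	70.7	NA
trial	B	30	cl_f	7836.7	61.5	NA
trial	C	39	auc_dw	116.3	59.3	NA
trial	C	39	cmax_dw	26.6	60.2	NA
trial	C	39	tmax	1.3	61.5	NA
trial	C	39	t_half	9.4	28.7	NA
trial	C	39	vd_f	147.1	53.0	NA
trial	C	39	cl_f	11036.7	45.7	NA
trial	D	37	auc_dw	149.4	46.3	NA
trial	D	37	cmax_dw	37.4	61.0	NA
trial	D	37	tmax	1.4	42.9	NA
trial	D	37	t_half	8.7	33.3	NA
trial	D	37	vd_f	103.9	71.9	NA
trial	D	37	cl_f	8247.0	45.9	NA
trial	E	36	auc_dw	130.5	57.5	NA
trial	E	36	cmax_dw	33.7	82.2	NA
trial	E	36	tmax	1.4	42.9	NA
trial	E	36	t_half	9.5	30.5	NA
trial	E	36	vd_f	127.7	52.2	NA
trial	E	36	cl_f	9181.5	30.4	NA
ezetimibe	No	119	auc_dw	136.9	60.9	NA
ezetimibe	No	119	cmax_dw	30.7	69.1	NA
ezetimibe	No	119	tmax	1.4	64.3	NA
ezetimibe	No	119	t_half	9.2	27.2	NA
ezetimibe	No	119	vd_f	126.1	57.3	NA
ezetimibe	No	119	cl_f	9399.1	46.2	NA
ezetimibe	Yes	37	auc_dw	149.4	46.3	NA
ezetimibe	Yes	37	cmax_dw	37.4	61.0	NA
ezetimibe	Yes	37	tmax	1.4	42.9	NA
ezetimibe	Yes	37	t_half	8.7	33.3	NA
ezetimibe	Yes	37	vd_f	103.9	71.9	NA
ezetimibe	Yes	37	cl_f	8247.0	45.9	NA
race	Caucasian	81	auc_dw	132.5	61.1	NA
race	Caucasian	81	cmax_dw	33.5	71.6	NA
race	Caucasian	81	tmax	1.4	50.0	NA
race	Caucasian	81	t_half	9.5	29.5	NA
race	Caucasian	81	vd_f	138.1	63.8	NA
race	Caucasian	81	cl_f	9938.9	49.4	NA
race	Latin-American	70	auc_dw	147.8	54.2	NA
race	Latin-American	70	cmax_dw	31.0	62.9	NA
race	Latin-American	70	tmax	1.5	60.0	NA
race	Latin-American	70	t_half	8.7	27.6	NA
race	Latin-American	70	vd_f	103.4	45.9	NA
race	Latin-American	70	cl_f	8279.3	38.7	NA
race	Black or Arabic	5	auc_dw	148.7	48.4	NA
race	Black or Arabic	5	cmax_dw	31.8	34.3	NA
race	Black or Arabic	5	tmax	1.6	43.8	NA
race	Black or Arabic	5	t_half	7.6	9.2	NA
race	Black or Arabic	5	vd_f	83.8	33.4	NA
race	Black or Arabic	5	cl_f	7808.3	36.8	NA
slco1b1	NF	86	auc_dw	122.6	44.9	NA
slco1b1	NF	86	cmax_dw	28.5	59.3	NA
slco1b1	NF	86	tmax	1.4	64.3	NA
slco1b1	NF	86	t_half	9	30.0	NA
slco1b1	NF	86	vd_f	127.8	57.8	NA
slco1b1	NF	86	cl_f	9827.4	43.1	NA
slco1b1	DF	30	auc_dw	181.5	59.3	NA
slco1b1	DF	30	cmax_dw	37.5	60.0	NA
slco1b1	DF	30	tmax	1.4	57.1	NA
slco1b1	DF	30	t_half	8.7	25.3	NA
slco1b1	DF	30	vd_f	99.7	78.0	NA
slco1b1	DF	30	cl_f	7680.4	67.0	NA
slco1b1	PF	4	auc_dw	283.7	41.4	NA
slco1b1	PF	4	cmax_dw	62.4	35.9	NA
slco1b1	PF	4	tmax	1.3	38.5	NA
slco1b1	PF	4	t_half	10.5	9.5	NA
slco1b1	PF	4	vd_f	66.4	58.9	NA
slco1b1	PF	4	cl_f	4382.7	60.2	NA
cyp3a5_star3	*1/*1	5	auc_dw	244.2	21.5	NA
cyp3a5_star3	*1/*1	5	cmax_dw	57.1	55.2	NA
cyp3a5_star3	*1/*1	5	tmax	1.9	42.1	NA
cyp3a5_star3	*1/*1	5	t_half	9.8	26.5	NA
cyp3a5_star3	*1/*1	5	vd_f	65.2	41.9	NA
cyp3a5_star3	*1/*1	5	cl_f	4405.1	23.7	NA
cyp3a5_star3	*1/*3	32	auc_dw	153.7	70.3	NA
cyp3a5_star3	*1/*3	32	cmax_dw	35.1	75.5	NA
cyp3a5_star3	*1/*3	32	tmax	1.4	71.4	NA
cyp3a5_star3	*1/*3	32	t_half	8.8	21.6	NA
cyp3a5_star3	*1/*3	32	vd_f	114.3	60.6	NA
cyp3a5_star3	*1/*3	32	cl_f	9181.8	55.0	NA
cyp3a5_star3	*3/*3	119	auc_dw	131.8	52.0	NA
cyp3a5_star3	*3/*3	119	cmax_dw	30.5	63.0	NA
cyp3a5_star3	*3/*3	119	tmax	1.4	50.0	NA
cyp3a5_star3	*3/*3	119	t_half	9.1	30.8	NA
cyp3a5_star3	*3/*3	119	vd_f	124.9	59.9	NA
cyp3a5_star3	*3/*3	119	cl_f	9309.2	42.7	NA
slc22a1_star2	*1/*1	71	auc_dw	131.8	48.7	NA
slc22a1_star2	*1/*1	71	cmax_dw	28.9	53.6	NA
slc22a1_star2	*1/*1	71	tmax	1.4	57.1	NA
slc22a1_star2	*1/*1	71	t_half	8.9	29.2	NA
slc22a1_star2	*1/*1	71	vd_f	121.4	57.5	NA
slc22a1_star2	*1/*1	71	cl_f	9393.2	47.7	NA
slc22a1_star2	*1/*2	41	auc_dw	151.2	66.2	NA
slc22a1_star2	*1/*2	41	cmax_dw	33.5	64.5	NA
slc22a1_star2	*1/*2	41	tmax	1.4	64.3	NA
slc22a1_star2	*1/*2	41	t_half	9	28.9	NA
slc22a1_star2	*1/*2	41	vd_f	121.1	72.0	NA
slc22a1_star2	*1/*2	41	cl_f	9136.4	54.0	NA
slc22a1_star2	*2/*2	8	auc_dw	195.7	51.8	NA
slc22a1_star2	*2/*2	8	cmax_dw	49.8	64.7	NA
slc22a1_star2	*2/*2	8	tmax	1.6	68.8	NA
slc22a1_star2	*2/*2	8	t_half	8.9	19.1	NA
slc22a1_star2	*2/*2	8	vd_f	83	59.5	NA
slc22a1_star2	*2/*2	8	cl_f	6449.1	47.9	NA
slc22a1_star5	*1/*1	114	auc_dw	144.6	57.0	NA
slc22a1_star5	*1/*1	114	cmax_dw	32.3	61.9	NA
slc22a1_star5	*1/*1	114	tmax	1.4	64.3	NA
slc22a1_star5	*1/*1	114	t_half	8.9	28.1	NA
slc22a1_star5	*1/*1	114	vd_f	114.8	59.7	NA
slc22a1_star5	*1/*1	114	cl_f	8933.1	49.3	NA
slc22a1_star5	*1/*5	6	auc_dw	105.6	58.4	NA
slc22a1_star5	*1/*5	6	cmax_dw	24.2	34.3	NA
slc22a1_star5	*1/*5	6	tmax	1.6	43.8	NA
slc22a1_star5	*1/*5	6	t_half	10.8	30.6	NA
slc22a1_star5	*1/*5	6	vd_f	193.9	75.6	NA
slc22a1_star5	*1/*5	6	cl_f	12455.2	56.3	NA
ugt2b7_rs7439366	*1/*1	9	auc_dw	159.6	80.6	NA
ugt2b7_rs7439366	*1/*1	9	cmax_dw	44.1	103.9	NA
ugt2b7_rs7439366	*1/*1	9	tmax	1.8	44.4	NA
ugt2b7_rs7439366	*1/*1	9	t_half	8.2	24.4	NA
ugt2b7_rs7439366	*1/*1	9	vd_f	106.9	50.4	NA
ugt2b7_rs7439366	*1/*1	9	cl_f	8821	43.8	NA
ugt2b7_rs7439366	*1/*2	12	auc_dw	108.9	29.5	NA
ugt2b7_rs7439366	*1/*2	12	cmax_dw	26.6	35.3	NA
ugt2b7_rs7439366	*1/*2	12	tmax	1.1	36.4	NA
ugt2b7_rs7439366	*1/*2	12	t_half	9.5	22.1	NA
ugt2b7_rs7439366	*1/*2	12	vd_f	137.8	35.6	NA
ugt2b7_rs7439366	*1/*2	12	cl_f	9990.2	22.7	NA
ugt2b7_rs7439366	*2/*2	15	auc_dw	130.4	41.1	NA
ugt2b7_rs7439366	*2/*2	15	cmax_dw	33.2	69.3	NA
ugt2b7_rs7439366	*2/*2	15	tmax	1.4	28.6	NA
ugt2b7_rs7439366	*2/*2	15	t_half	10.1	36.6	NA
ugt2b7_rs7439366	*2/*2	15	vd_f	132	64.2	NA
ugt2b7_rs7439366	*2/*2	15	cl_f	8751	28.3	NA
overall	Total	156	auc_dw	139.9	57.3	NA
overall	Total	156	cmax_dw	32.3	67.2	NA
overall	Total	156	tmax	1.4	57.1	NA
overall	Total	156	t_half	9.1	28.6	NA
overall	Total	156	vd_f	120.8	60.6	NA
overall	Total	156	cl_f	9125.9	46.4	NA
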