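# schema_version: 1
# Demographic summary statistics of the reference atorvastatin cohort
# (156 healthy volunteers, 85 women / 71 men; inclusion criteria age 18-55,
# BMI 18-30 kg/m2). Means with CV% (100*SD/mean).
# weight kg, bmi kg/m2, height m, age years.
stratifier	level	n	parameter	mean	cv
sex	Female	85	weight	61.5	13.8
sex	Female	85	bmi	23.1	13.4
sex	Female	85	height	1.63	3.7
sex	Female	85	age	30.1	28.2
sex	Male	71	weight	75.3	12.7
sex	Male	71	bmi	24.4	10.2
sex	Male	71	height	1.75	4.0
sex	Male	71	age	27.8	27.0
race	Caucasian	81	weight	65.5	16.8
race	Caucasian	81	bmi	22.6	10.6
race	Caucasian	81	height	1.7	5.9
race	Caucasian	81	age	25.5	22.4
race	Latin-American	70	weight	69.2	15.0
race	Latin-American	70	bmi	24.8	11.7
race	Latin-American	70	height	1.67	6.0
race	Latin-American	70	age	32.7	26.9
race	Black or Arabic	5	weight	85.3	15.0
race	Black or Arabic	5	bmi	27.0	7.4
race	Black or Arabic	5	height	1.77	5.6
race	Black or Arabic	5	age	33.7	18.7
overall	Total	156	weight	67.7	16.8
overall	Total	156	bmi	23.7	12.2
overall	Total	156	height	1.69	5.9
overall	Total	156	age	29.0	27.9
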