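subject_id	sex	age	blood_group	wes_analyzed	fviii_c	fviii_ag	vwf_ag	vwf_rco	covariates
II-8	F	51	non-O	TRUE	415,389,398,549,239,269	520	308,151,210	209,133,157	obesity;diabetes;dyslipidemia;deep vein thrombosis;superficial thrombophlebitis
II-2	M	55	non-O	TRUE	180	195	185	120	overweight;diabetes
II-3	F	65	non-O	TRUE	317	336	295	234	obesity;diabetes;atrial fibrillation;pulmonary embolism
II-5	M	63	non-O	TRUE	397,225	458	390,210	307,157	overweight;diabetes;hypertension;carcinoma;superficial thrombophlebitis
II-6	M	57	O	TRUE	140	151	117	117	HIV
II-9	F	66	O	TRUE	188,189	194	194,203	145,176	obesity;iliac artery thrombosis
III-1	F	12	non-O	TRUE	142		111	103
III-2	M	19	non-O	TRUE	101		89	72
III-3	M	10	non-O	TRUE	200		227	146
III-5	F	31	O	TRUE	198	251	145	108	overweight
III-7	M	15	O	TRUE	79	97	71	61
III-8	F	30	O	TRUE	122	124	79	79
III-4	M		unknown	FALSE	164		126	123
III-6	M		unknown	FALSE	165		153	134
III-9	F		unknown	FALSE	165		132	122
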