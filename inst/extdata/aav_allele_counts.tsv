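locus	group	allele	count	total_2n	kind
DRB1	MPA	DRB1*01:01	41	570	allele
DRB1	MPA	DRB1*04:01	6	570	allele
DRB1	MPA	DRB1*04:03	14	570	allele
DRB1	MPA	DRB1*04:05	65	570	allele
DRB1	MPA	DRB1*04:06	12	570	allele
DRB1	MPA	DRB1*04:07	6	570	allele
DRB1	MPA	DRB1*04:10	9	570	allele
DRB1	MPA	DRB1*08:02	21	570	allele
DRB1	MPA	DRB1*08:03	41	570	allele
DRB1	MPA	DRB1*09:01	125	570	allele
DRB1	MPA	DRB1*11:01	16	570	allele
DRB1	MPA	DRB1*12:01	17	570	allele
DRB1	MPA	DRB1*12:02	8	570	allele
DRB1	MPA	DRB1*13:02	25	570	allele
DRB1	MPA	DRB1*14:03	17	570	allele
DRB1	MPA	DRB1*14:05	12	570	allele
DRB1	MPA	DRB1*14:06	4	570	allele
DRB1	MPA	DRB1*14:54	24	570	allele
DRB1	MPA	DRB1*15:01	28	570	allele
DRB1	MPA	DRB1*15:02	71	570	allele
DRB1	MPA	DRB1*16:02	1	570	allele
DPB1	MPA	DPB1*02:01	155	570	allele
DPB1	MPA	DPB1*02:02	24	570	allele
DPB1	MPA	DPB1*03:01	29	570	allele
DPB1	MPA	DPB1*04:01	19	570	allele
DPB1	MPA	DPB1*04:02	73	570	allele
DPB1	MPA	DPB1*05:01	183	570	allele
DPB1	MPA	DPB1*09:01	64	570	allele
DPB1	MPA	DPB1*13:01	6	570	allele
DPB1	MPA	DPB1*14:01	8	570	allele
DRB1	EGPA	DRB1*01:01	8	112	allele
DRB1	EGPA	DRB1*04:01	0	112	allele
DRB1	EGPA	DRB1*04:03	4	112	allele
DRB1	EGPA	DRB1*04:05	8	112	allele
DRB1	EGPA	DRB1*04:06	3	112	allele
DRB1	EGPA	DRB1*04:07	0	112	allele
DRB1	EGPA	DRB1*04:10	3	112	allele
DRB1	EGPA	DRB1*08:02	1	112	allele
DRB1	EGPA	DRB1*08:03	9	112	allele
DRB1	EGPA	DRB1*09:01	24	112	allele
DRB1	EGPA	DRB1*11:01	3	112	allele
DRB1	EGPA	DRB1*12:01	4	112	allele
DRB1	EGPA	DRB1*12:02	2	112	allele
DRB1	EGPA	DRB1*13:02	6	112	allele
DRB1	EGPA	DRB1*14:03	2	112	allele
DRB1	EGPA	DRB1*14:05	1	112	allele
DRB1	EGPA	DRB1*14:06	2	112	allele
DRB1	EGPA	DRB1*14:54	4	112	allele
DRB1	EGPA	DRB1*15:01	10	112	allele
DRB1	EGPA	DRB1*15:02	13	112	allele
DRB1	EGPA	DRB1*16:02	1	112	allele
DPB1	EGPA	DPB1*02:01	23	112	allele
DPB1	EGPA	DPB1*02:02	4	112	allele
DPB1	EGPA	DPB1*03:01	4	112	allele
DPB1	EGPA	DPB1*04:01	2	112	allele
DPB1	EGPA	DPB1*04:02	14	112	allele
DPB1	EGPA	DPB1*05:01	43	112	allele
DPB1	EGPA	DPB1*09:01	11	112	allele
DPB1	EGPA	DPB1*13:01	5	112	allele
DPB1	EGPA	DPB1*14:01	0	112	allele
DRB1	GPA	DRB1*01:01	14	184	allele
DRB1	GPA	DRB1*04:01	2	184	allele
DRB1	GPA	DRB1*04:03	3	184	allele
DRB1	GPA	DRB1*04:05	24	184	allele
DRB1	GPA	DRB1*04:06	7	184	allele
DRB1	GPA	DRB1*04:07	2	184	allele
DRB1	GPA	DRB1*04:10	4	184	allele
DRB1	GPA	DRB1*08:02	13	184	allele
DRB1	GPA	DRB1*08:03	15	184	allele
DRB1	GPA	DRB1*09:01	35	184	allele
DRB1	GPA	DRB1*11:01	5	184	allele
DRB1	GPA	DRB1*12:01	2	184	allele
DRB1	GPA	DRB1*12:02	1	184	allele
DRB1	GPA	DRB1*13:02	9	184	allele
DRB1	GPA	DRB1*14:03	1	184	allele
DRB1	GPA	DRB1*14:05	3	184	allele
DRB1	GPA	DRB1*14:06	2	184	allele
DRB1	GPA	DRB1*14:54	3	184	allele
DRB1	GPA	DRB1*15:01	9	184	allele
DRB1	GPA	DRB1*15:02	25	184	allele
DRB1	GPA	DRB1*16:02	3	184	allele
DPB1	GPA	DPB1*02:01	50	184	allele
DPB1	GPA	DPB1*02:02	4	184	allele
DPB1	GPA	DPB1*03:01	6	184	allele
DPB1	GPA	DPB1*04:01	14	184	allele
DPB1	GPA	DPB1*04:02	19	184	allele
DPB1	GPA	DPB1*05:01	64	184	allele
DPB1	GPA	DPB1*09:01	19	184	allele
DPB1	GPA	DPB1*13:01	1	184	allele
DPB1	GPA	DPB1*14:01	5	184	allele
DRB1	HC	DRB1*01:01	70	1192	allele
DRB1	HC	DRB1*04:01	17	1192	allele
DRB1	HC	DRB1*04:03	36	1192	allele
DRB1	HC	DRB1*04:05	151	1192	allele
DRB1	HC	DRB1*04:06	39	1192	allele
DRB1	HC	DRB1*04:07	12	1192	allele
DRB1	HC	DRB1*04:10	17	1192	allele
DRB1	HC	DRB1*08:02	33	1192	allele
DRB1	HC	DRB1*08:03	87	1192	allele
DRB1	HC	DRB1*09:01	182	1192	allele
DRB1	HC	DRB1*11:01	21	1192	allele
DRB1	HC	DRB1*12:01	48	1192	allele
DRB1	HC	DRB1*12:02	23	1192	allele
DRB1	HC	DRB1*13:02	106	1192	allele
DRB1	HC	DRB1*14:03	27	1192	allele
DRB1	HC	DRB1*14:05	34	1192	allele
DRB1	HC	DRB1*14:06	12	1192	allele
DRB1	HC	DRB1*14:54	33	1192	allele
DRB1	HC	DRB1*15:01	81	1192	allele
DRB1	HC	DRB1*15:02	130	1192	allele
DRB1	HC	DRB1*16:02	12	1192	allele
DPB1	HC	DPB1*02:01	284	1186	allele
DPB1	HC	DPB1*02:02	38	1186	allele
DPB1	HC	DPB1*03:01	45	1186	allele
DPB1	HC	DPB1*04:01	75	1186	allele
DPB1	HC	DPB1*04:02	110	1186	allele
DPB1	HC	DPB1*05:01	452	1186	allele
DPB1	HC	DPB1*09:01	122	1186	allele
DPB1	HC	DPB1*13:01	22	1186	allele
DPB1	HC	DPB1*14:01	21	1186	allele
DRB1	MPO-AAV	DRB1*01:01	56	754	allele
DRB1	MPO-AAV	DRB1*04:01	7	754	allele
DRB1	MPO-AAV	DRB1*04:03	18	754	allele
DRB1	MPO-AAV	DRB1*04:05	74	754	allele
DRB1	MPO-AAV	DRB1*04:06	24	754	allele
DRB1	MPO-AAV	DRB1*04:07	7	754	allele
DRB1	MPO-AAV	DRB1*04:10	12	754	allele
DRB1	MPO-AAV	DRB1*08:02	36	754	allele
DRB1	MPO-AAV	DRB1*08:03	51	754	allele
DRB1	MPO-AAV	DRB1*09:01	166	754	allele
DRB1	MPO-AAV	DRB1*11:01	19	754	allele
DRB1	MPO-AAV	DRB1*12:01	20	754	allele
DRB1	MPO-AAV	DRB1*12:02	6	754	allele
DRB1	MPO-AAV	DRB1*13:02	30	754	allele
DRB1	MPO-AAV	DRB1*14:03	21	754	allele
DRB1	MPO-AAV	DRB1*14:05	13	754	allele
DRB1	MPO-AAV	DRB1*14:06	8	754	allele
DRB1	MPO-AAV	DRB1*14:54	28	754	allele
DRB1	MPO-AAV	DRB1*15:01	43	754	allele
DRB1	MPO-AAV	DRB1*15:02	97	754	allele
DRB1	MPO-AAV	DRB1*16:02	5	754	allele
DPB1	MPO-AAV	DPB1*02:01	200	754	allele
DPB1	MPO-AAV	DPB1*02:02	29	754	allele
DPB1	MPO-AAV	DPB1*03:01	37	754	allele
DPB1	MPO-AAV	DPB1*04:01	20	754	allele
DPB1	MPO-AAV	DPB1*04:02	91	754	allele
DPB1	MPO-AAV	DPB1*05:01	255	754	allele
DPB1	MPO-AAV	DPB1*09:01	88	754	allele
DPB1	MPO-AAV	DPB1*13:01	10	754	allele
DPB1	MPO-AAV	DPB1*14:01	11	754	allele
DRB1	PR3-AAV	DRB1*01:01	8	124	allele
DRB1	PR3-AAV	DRB1*04:01	2	124	allele
DRB1	PR3-AAV	DRB1*04:03	2	124	allele
DRB1	PR3-AAV	DRB1*04:05	17	124	allele
DRB1	PR3-AAV	DRB1*04:06	1	124	allele
DRB1	PR3-AAV	DRB1*04:07	2	124	allele
DRB1	PR3-AAV	DRB1*04:10	3	124	allele
DRB1	PR3-AAV	DRB1*08:02	2	124	allele
DRB1	PR3-AAV	DRB1*08:03	14	124	allele
DRB1	PR3-AAV	DRB1*09:01	23	124	allele
DRB1	PR3-AAV	DRB1*11:01	5	124	allele
DRB1	PR3-AAV	DRB1*12:01	3	124	allele
DRB1	PR3-AAV	DRB1*12:02	2	124	allele
DRB1	PR3-AAV	DRB1*13:02	9	124	allele
DRB1	PR3-AAV	DRB1*14:03	0	124	allele
DRB1	PR3-AAV	DRB1*14:05	4	124	allele
DRB1	PR3-AAV	DRB1*14:06	1	124	allele
DRB1	PR3-AAV	DRB1*14:54	5	124	allele
DRB1	PR3-AAV	DRB1*15:01	6	124	allele
DRB1	PR3-AAV	DRB1*15:02	14	124	allele
DRB1	PR3-AAV	DRB1*16:02	0	124	allele
DPB1	PR3-AAV	DPB1*02:01	29	124	allele
DPB1	PR3-AAV	DPB1*02:02	3	124	allele
DPB1	PR3-AAV	DPB1*03:01	4	124	allele
DPB1	PR3-AAV	DPB1*04:01	14	124	allele
DPB1	PR3-AAV	DPB1*04:02	14	124	allele
DPB1	PR3-AAV	DPB1*05:01	45	124	allele
DPB1	PR3-AAV	DPB1*09:01	9	124	allele
DPB1	PR3-AAV	DPB1*13:01	0	124	allele
DPB1	PR3-AAV	DPB1*14:01	3	124	allele
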