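locus	group	allele	or	ci_low	ci_high	p	p_rpe	haldane
DRB1	MPA	DRB1*01:01	1.24	0.83	1.85	0.30		FALSE
DRB1	MPA	DRB1*04:01	0.74	0.29	1.88	0.66		FALSE
DRB1	MPA	DRB1*04:03	0.81	0.43	1.51	0.54		FALSE
DRB1	MPA	DRB1*04:05	0.89	0.65	1.21	0.49		FALSE
DRB1	MPA	DRB1*04:06	0.64	0.33	1.22	0.22		FALSE
DRB1	MPA	DRB1*04:07	1.05	0.39	2.8	1.0		FALSE
DRB1	MPA	DRB1*04:10	1.11	0.49	2.5	0.83		FALSE
DRB1	MPA	DRB1*08:02	1.34	0.77	2.34	0.30		FALSE
DRB1	MPA	DRB1*08:03	0.98	0.67	1.45	1.0		FALSE
DRB1	MPA	DRB1*09:01	1.56	1.21	2.01	7.7E-04		FALSE
DRB1	MPA	DRB1*11:01	1.61	0.83	3.11	0.16		FALSE
DRB1	MPA	DRB1*12:01	0.73	0.42	1.29	0.34		FALSE
DRB1	MPA	DRB1*12:02	0.72	0.32	1.63	0.56		FALSE
DRB1	MPA	DRB1*13:02	0.47	0.3	0.74	6.3E-04		FALSE
DRB1	MPA	DRB1*14:03	1.33	0.72	2.45	0.41		FALSE
DRB1	MPA	DRB1*14:05	0.73	0.38	1.43	0.43		FALSE
DRB1	MPA	DRB1*14:06	0.69	0.22	2.16	0.60		FALSE
DRB1	MPA	DRB1*14:54	1.54	0.9	2.64	0.11		FALSE
DRB1	MPA	DRB1*15:01	0.71	0.46	1.1	0.14		FALSE
DRB1	MPA	DRB1*15:02	1.16	0.85	1.58	0.34		FALSE
DRB1	MPA	DRB1*16:02	0.17	0.02	1.33	0.073		FALSE
DRB1	EGPA	DRB1*01:01	1.23	0.58	2.63	0.53		FALSE
DRB1	EGPA	DRB1*04:01	0.3	0.02	5	0.39		TRUE
DRB1	EGPA	DRB1*04:03	1.19	0.42	3.4	0.77		FALSE
DRB1	EGPA	DRB1*04:05	0.53	0.25	1.11	0.097		FALSE
DRB1	EGPA	DRB1*04:06	0.81	0.25	2.68	1.0		FALSE
DRB1	EGPA	DRB1*04:07	0.42	0.02	7.14	0.61		TRUE
DRB1	EGPA	DRB1*04:10	1.9	0.55	6.59	0.24		FALSE
DRB1	EGPA	DRB1*08:02	0.32	0.04	2.34	0.35		FALSE
DRB1	EGPA	DRB1*08:03	1.11	0.54	2.27	0.71		FALSE
DRB1	EGPA	DRB1*09:01	1.51	0.94	2.44	0.10		FALSE
DRB1	EGPA	DRB1*11:01	1.53	0.45	5.23	0.45		FALSE
DRB1	EGPA	DRB1*12:01	0.88	0.31	2.49	1.0		FALSE
DRB1	EGPA	DRB1*12:02	0.92	0.22	3.97	1.0		FALSE
DRB1	EGPA	DRB1*13:02	0.58	0.25	1.35	0.29		FALSE
DRB1	EGPA	DRB1*14:03	0.78	0.18	3.34	1.0		FALSE
DRB1	EGPA	DRB1*14:05	0.31	0.04	2.26	0.36		FALSE
DRB1	EGPA	DRB1*14:06	1.79	0.4	8.09	0.34		FALSE
DRB1	EGPA	DRB1*14:54	1.3	0.45	3.74	0.55		FALSE
DRB1	EGPA	DRB1*15:01	1.34	0.68	2.67	0.43		FALSE
DRB1	EGPA	DRB1*15:02	1.07	0.59	1.97	0.75		FALSE
DRB1	EGPA	DRB1*16:02	0.89	0.11	6.88	1.0		FALSE
DRB1	GPA	DRB1*01:01	1.32	0.73	2.4	0.41		FALSE
DRB1	GPA	DRB1*04:01	0.76	0.17	3.31	1.0		FALSE
DRB1	GPA	DRB1*04:03	0.53	0.16	1.75	0.47		FALSE
DRB1	GPA	DRB1*04:05	1.03	0.65	1.64	0.91		FALSE
DRB1	GPA	DRB1*04:06	1.17	0.51	2.65	0.66		FALSE
DRB1	GPA	DRB1*04:07	1.08	0.24	4.87	1.0		FALSE
DRB1	GPA	DRB1*04:10	1.54	0.51	4.62	0.51		FALSE
DRB1	GPA	DRB1*08:02	2.67	1.38	5.17	0.0064		FALSE
DRB1	GPA	DRB1*08:03	1.13	0.64	2	0.65		FALSE
DRB1	GPA	DRB1*09:01	1.3	0.87	1.95	0.19		FALSE
DRB1	GPA	DRB1*11:01	1.56	0.58	4.18	0.38		FALSE
DRB1	GPA	DRB1*12:01	0.26	0.06	1.09	0.054		FALSE
DRB1	GPA	DRB1*12:02	0.28	0.04	2.07	0.24		FALSE
DRB1	GPA	DRB1*13:02	0.53	0.26	1.06	0.084		FALSE
DRB1	GPA	DRB1*14:03	0.24	0.03	1.75	0.16		FALSE
DRB1	GPA	DRB1*14:05	0.56	0.17	1.86	0.47		FALSE
DRB1	GPA	DRB1*14:06	1.08	0.24	4.87	1.0		FALSE
DRB1	GPA	DRB1*14:54	0.58	0.18	1.92	0.47		FALSE
DRB1	GPA	DRB1*15:01	0.71	0.35	1.43	0.42		FALSE
DRB1	GPA	DRB1*15:02	1.28	0.81	2.03	0.32		FALSE
DRB1	GPA	DRB1*16:02	1.63	0.46	5.83	0.44		FALSE
DRB1	MPO-AAV	DRB1*01:01	1.29	0.89	1.85	0.19	0.30	FALSE
DRB1	MPO-AAV	DRB1*04:01	0.65	0.27	1.57	0.40	0.30	FALSE
DRB1	MPO-AAV	DRB1*04:03	0.79	0.44	1.39	0.48	0.33	FALSE
DRB1	MPO-AAV	DRB1*04:05	0.75	0.56	1.01	0.059	0.020	FALSE
DRB1	MPO-AAV	DRB1*04:06	0.97	0.58	1.63	1.0	0.79	FALSE
DRB1	MPO-AAV	DRB1*04:07	0.92	0.36	2.35	1.0	0.82	FALSE
DRB1	MPO-AAV	DRB1*04:10	1.12	0.53	2.35	0.85	1.0	FALSE
DRB1	MPO-AAV	DRB1*08:02	1.76	1.09	2.85	0.023	0.044	FALSE
DRB1	MPO-AAV	DRB1*08:03	0.92	0.64	1.32	0.72	0.47	FALSE
DRB1	MPO-AAV	DRB1*09:01	1.57	1.24	1.98	2.1E-04	0.0012	FALSE
DRB1	MPO-AAV	DRB1*11:01	1.44	0.77	2.7	0.26	0.33	FALSE
DRB1	MPO-AAV	DRB1*12:01	0.65	0.38	1.1	0.13	0.077	FALSE
DRB1	MPO-AAV	DRB1*12:02	0.41	0.17	1.01	0.054	0.035	FALSE
DRB1	MPO-AAV	DRB1*13:02	0.42	0.28	0.64	2.3E-05		FALSE
DRB1	MPO-AAV	DRB1*14:03	1.24	0.69	2.2	0.55	0.65	FALSE
DRB1	MPO-AAV	DRB1*14:05	0.6	0.31	1.14	0.13	0.097	FALSE
DRB1	MPO-AAV	DRB1*14:06	1.05	0.43	2.59	1.0	1.0	FALSE
DRB1	MPO-AAV	DRB1*14:54	1.35	0.81	2.26	0.29	0.35	FALSE
DRB1	MPO-AAV	DRB1*15:01	0.83	0.57	1.21	0.39	0.22	FALSE
DRB1	MPO-AAV	DRB1*15:02	1.21	0.91	1.6	0.19	0.39	FALSE
DRB1	MPO-AAV	DRB1*16:02	0.66	0.23	1.87	0.62	0.46	FALSE
DRB1	PR3-AAV	DRB1*01:01	1.11	0.52	2.35	0.84		FALSE
DRB1	PR3-AAV	DRB1*04:01	1.13	0.26	4.96	0.70		FALSE
DRB1	PR3-AAV	DRB1*04:03	0.53	0.13	2.21	0.57		FALSE
DRB1	PR3-AAV	DRB1*04:05	1.1	0.64	1.88	0.78		FALSE
DRB1	PR3-AAV	DRB1*04:06	0.24	0.03	1.76	0.17		FALSE
DRB1	PR3-AAV	DRB1*04:07	1.61	0.36	7.29	0.39		FALSE
DRB1	PR3-AAV	DRB1*04:10	1.71	0.5	5.93	0.43		FALSE
DRB1	PR3-AAV	DRB1*08:02	0.58	0.14	2.43	0.77		FALSE
DRB1	PR3-AAV	DRB1*08:03	1.62	0.89	2.94	0.11		FALSE
DRB1	PR3-AAV	DRB1*09:01	1.26	0.78	2.04	0.36		FALSE
DRB1	PR3-AAV	DRB1*11:01	2.34	0.87	6.33	0.090		FALSE
DRB1	PR3-AAV	DRB1*12:01	0.59	0.18	1.93	0.62		FALSE
DRB1	PR3-AAV	DRB1*12:02	0.83	0.19	3.58	1.0		FALSE
DRB1	PR3-AAV	DRB1*13:02	0.8	0.4	1.63	0.62		FALSE
DRB1	PR3-AAV	DRB1*14:03	0.17	0.01	2.81	0.10		TRUE
DRB1	PR3-AAV	DRB1*14:05	1.14	0.4	3.25	0.78		FALSE
DRB1	PR3-AAV	DRB1*14:06	0.8	0.1	6.2	1.0		FALSE
DRB1	PR3-AAV	DRB1*14:54	1.48	0.57	3.85	0.40		FALSE
DRB1	PR3-AAV	DRB1*15:01	0.7	0.3	1.63	0.57		FALSE
DRB1	PR3-AAV	DRB1*15:02	1.04	0.58	1.87	0.88		FALSE
DRB1	PR3-AAV	DRB1*16:02	0.38	0.02	6.44	0.62		TRUE
DPB1	MPA	DPB1*02:01	1.19	0.94	1.49	0.14		FALSE
DPB1	MPA	DPB1*02:02	1.33	0.79	2.24	0.33		FALSE
DPB1	MPA	DPB1*03:01	1.36	0.84	2.19	0.21		FALSE
DPB1	MPA	DPB1*04:01	0.51	0.31	0.85	0.0090		FALSE
DPB1	MPA	DPB1*04:02	1.44	1.05	1.97	0.025		FALSE
DPB1	MPA	DPB1*05:01	0.77	0.62	0.95	0.015		FALSE
DPB1	MPA	DPB1*09:01	1.1	0.8	1.52	0.56		FALSE
DPB1	MPA	DPB1*13:01	0.56	0.23	1.4	0.31		FALSE
DPB1	MPA	DPB1*14:01	0.79	0.35	1.79	0.69		FALSE
DPB1	EGPA	DPB1*02:01	0.82	0.51	1.32	0.49		FALSE
DPB1	EGPA	DPB1*02:02	1.12	0.39	3.19	0.78		FALSE
DPB1	EGPA	DPB1*03:01	0.94	0.33	2.66	1.0		FALSE
DPB1	EGPA	DPB1*04:01	0.27	0.07	1.11	0.057		FALSE
DPB1	EGPA	DPB1*04:02	1.4	0.77	2.53	0.31		FALSE
DPB1	EGPA	DPB1*05:01	1.01	0.68	1.51	1.0		FALSE
DPB1	EGPA	DPB1*09:01	0.95	0.5	1.82	1.0		FALSE
DPB1	EGPA	DPB1*13:01	2.47	0.92	6.66	0.076		FALSE
DPB1	EGPA	DPB1*14:01	0.24	0.01	4	0.25		TRUE
DPB1	GPA	DPB1*02:01	1.19	0.83	1.68	0.36		FALSE
DPB1	GPA	DPB1*02:02	0.67	0.24	1.9	0.64		FALSE
DPB1	GPA	DPB1*03:01	0.85	0.36	2.03	0.84		FALSE
DPB1	GPA	DPB1*04:01	1.22	0.67	2.21	0.52		FALSE
DPB1	GPA	DPB1*04:02	1.13	0.67	1.88	0.68		FALSE
DPB1	GPA	DPB1*05:01	0.87	0.63	1.2	0.41		FALSE
DPB1	GPA	DPB1*09:01	1	0.6	1.67	1.0		FALSE
DPB1	GPA	DPB1*13:01	0.29	0.04	2.16	0.35		FALSE
DPB1	GPA	DPB1*14:01	1.55	0.58	4.16	0.38		FALSE
DPB1	MPO-AAV	DPB1*02:01	1.15	0.93	1.41	0.22	0.45	FALSE
DPB1	MPO-AAV	DPB1*02:02	1.21	0.74	1.98	0.45	0.61	FALSE
DPB1	MPO-AAV	DPB1*03:01	1.31	0.84	2.04	0.25	0.36	FALSE
DPB1	MPO-AAV	DPB1*04:01	0.4	0.24	0.67	2.1E-04		FALSE
DPB1	MPO-AAV	DPB1*04:02	1.34	1	1.8	0.056	0.094	FALSE
DPB1	MPO-AAV	DPB1*05:01	0.83	0.69	1	0.059	0.011	FALSE
DPB1	MPO-AAV	DPB1*09:01	1.15	0.86	1.54	0.37	0.50	FALSE
DPB1	MPO-AAV	DPB1*13:01	0.71	0.33	1.51	0.47	0.37	FALSE
DPB1	MPO-AAV	DPB1*14:01	0.82	0.39	1.71	0.72	0.59	FALSE
DPB1	PR3-AAV	DPB1*02:01	0.97	0.63	1.5	1.0		FALSE
DPB1	PR3-AAV	DPB1*02:02	0.75	0.23	2.46	0.79		FALSE
DPB1	PR3-AAV	DPB1*03:01	0.85	0.3	2.39	1.0		FALSE
DPB1	PR3-AAV	DPB1*04:01	1.89	1.03	3.45	0.057		FALSE
DPB1	PR3-AAV	DPB1*04:02	1.24	0.69	2.25	0.42		FALSE
DPB1	PR3-AAV	DPB1*05:01	0.93	0.63	1.36	0.77		FALSE
DPB1	PR3-AAV	DPB1*09:01	0.68	0.34	1.38	0.35		FALSE
DPB1	PR3-AAV	DPB1*13:01	0.21	0.01	3.45	0.26		TRUE
DPB1	PR3-AAV	DPB1*14:01	1.38	0.4	4.68	0.49		FALSE
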