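patient	region	total	shared	printed_percent	consistent
Patient1	ovary	36	17	47.22	TRUE
Patient1	omentum	40	24	60.00	TRUE
Patient1	bowel	39	22	56.41	TRUE
Patient1	all	59	13	22.03	TRUE
Patient2	ovary	47	24	51.06	TRUE
Patient2	omentum	51	21	41.18	TRUE
Patient2	bowel	46	26	45.52	FALSE
Patient2	all	76	19	25.00	TRUE
Patient3	ovary	32	14	43.75	TRUE
Patient3	omentum	34	19	55.88	TRUE
Patient3	bowel	46	7	15.22	TRUE
Patient3	all	94	2	2.13	TRUE
Patient4	ovary	50	17	34.00	TRUE
Patient4	omentum	18	4	22.22	TRUE
Patient4	bowel	48	22	45.83	TRUE
Patient4	all	62	4	6.45	TRUE
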