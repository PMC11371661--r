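#Published group-level summaries of a three-group cerebral small vessel disease cohort
#(severe burden CSVD-s n=54, mild burden CSVD-m n=106, healthy controls HC n=79).
#type=continuous rows carry mean/sd; type=binary rows carry count of positives.
#Binary markers scored only in patient groups have NA in the HC column.
variable	type	CSVD-s_n	CSVD-m_n	HC_n	CSVD-s_mean	CSVD-m_mean	HC_mean	CSVD-s_sd	CSVD-m_sd	HC_sd	CSVD-s_count	CSVD-m_count	HC_count
age	continuous	54	106	79	63.89	61.58	60.48	6.12	7.65	9.91	NA	NA	NA
education	continuous	54	106	79	11.22	12.12	12.66	3.31	3.19	3.49	NA	NA	NA
MoCA	continuous	54	106	79	24.39	25.38	26.19	2.89	3.59	3.76	NA	NA	NA
AVLT	continuous	54	106	79	54.96	61.25	64.00	13.29	12.55	12.36	NA	NA	NA
SCWT	continuous	54	106	79	179.8	146.21	133.53	58.93	44.79	37.93	NA	NA	NA
SDMT	continuous	54	106	79	26.18	32.18	40.42	11.85	12.43	14.33	NA	NA	NA
TMT	continuous	54	106	79	165.51	124.9	110.64	93.55	107.68	96.73	NA	NA	NA
head_motion	continuous	54	106	79	0.13	0.12	0.11	0.04	0.04	0.04	NA	NA	NA
male	binary	54	106	79	NA	NA	NA	NA	NA	NA	34	58	35
hypertension	binary	54	106	79	NA	NA	NA	NA	NA	NA	40	52	27
diabetes	binary	54	106	79	NA	NA	NA	NA	NA	NA	24	49	29
hyperlipidemia	binary	54	106	79	NA	NA	NA	NA	NA	NA	27	41	31
smoking	binary	54	106	79	NA	NA	NA	NA	NA	NA	16	26	22
lacunes	binary	54	106	NA	NA	NA	NA	NA	NA	NA	23	2	NA
WMH	binary	54	106	NA	NA	NA	NA	NA	NA	NA	46	21	NA
PVS	binary	54	106	NA	NA	NA	NA	NA	NA	NA	48	34	NA
CMB	binary	54	106	NA	NA	NA	NA	NA	NA	NA	35	13	NA
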