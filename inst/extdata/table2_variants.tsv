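gene_symbol	entrez_id	substitution	disease_associated	fc_score	fc_prediction	pph2_score	pph2_prediction	provean_score	provean_prediction	in_aligned_region
CASK	8573	T573I	No	0.6	Damaging	0.021	Neutral	-2.35	Neutral	No
CASK	8573	D471N	No	0.4	Neutral	0.005	Neutral	-1.48	Neutral	No
CASK	8573	M438L	No	0.4	Neutral	0	Neutral	-1.24	Neutral	Yes
CASK	8573	R430C	No	0.4	Neutral	0.035	Neutral	-2.51	Damaging	Yes
CASK	8573	R28L	Yes	0.8	Damaging	1	Damaging	-3.59	Damaging	Yes
CYP19A1	1588	M21T	No	0.6	Damaging	0.01	Neutral	-0.65	Neutral	No
CYP19A1	1588	M85R	Yes	0.8	Damaging	0.128	Neutral	-2.77	Damaging	Yes
CYP19A1	1588	W39R	No	0.4	Neutral	0.343	Neutral	-5.16	Damaging	Yes
CYP19A1	1588	M127R	Yes	0.8	Damaging	1	Damaging	-4.87	Damaging	Yes
CYP19A1	1588	Y81C	Yes	0.8	Damaging	1	Damaging	-6.87	Damaging	Yes
DHDDS	79947	K42E	Yes	0	Neutral	0.786	Damaging	-3.65	Damaging	Yes
EMG1	10436	D86G	Yes	0.6	Damaging	1	Damaging	-6.99	Damaging	Yes
IFT122	55764	G51A	No	0.2	Neutral	0.016	Neutral	-4.11	Damaging	No
IFT122	55764	T91I	No	0.2	Neutral	0.953	Damaging	-3.99	Damaging	No
IFT122	55764	S373F	Yes	0.6	Damaging	0.951	Damaging	-5.038	Damaging	No
IFT122	55764	L99W	No	0.4	Neutral	0.861	Damaging	-0.178	Neutral	No
IFT122	55764	R328W	No	0.2	Neutral	0.994	Damaging	-6.168	Damaging	No
RAB33B	83452	N148K	Yes	0.8	Damaging	0.005	Neutral	0.6	Neutral	No
RAB33B	83452	K46Q	Yes	0.8	Damaging	1	Damaging	-3.55	Damaging	Yes
RAB33B	83452	P142L	No	0.6	Damaging	1	Damaging	-9.99	Damaging	Yes
RAB33B	83452	T177M	No	0.6	Damaging	1	Damaging	-5.21	Damaging	Yes
VCP	7415	A232G	Yes	0.6	Damaging	0.005	Neutral	-1.87	Neutral	No
VCP	7415	I151V	Yes	0.4	Neutral	0	Neutral	-0.51	Neutral	Yes
VCP	7415	I27V	No	0.2	Neutral	0	Neutral	-0.43	Neutral	Yes
VCP	7415	Q19R	No	0.4	Neutral	0	Neutral	0.61	Neutral	Yes
VCP	7415	S171N	No	0	Neutral	0.004	Neutral	-1.18	Neutral	No
VCP	7415	T436I	No	0.4	Neutral	0.236	Neutral	-3.76	Damaging	No
VCP	7415	I206F	Yes	0.6	Damaging	0.983	Damaging	-3.7	Damaging	Yes
VCP	7415	L198W	Yes	0.6	Damaging	1	Damaging	-4.71	Damaging	Yes
VCP	7415	R159G	Yes	0.6	Damaging	1	Damaging	-6.56	Damaging	No
VCP	7415	R159C	Yes	0.8	Damaging	1	Damaging	-6.31	Damaging	No
VCP	7415	R159H	Yes	0.8	Damaging	0.517	Damaging	-2.97	Damaging	No
VCP	7415	R191G	Yes	0.6	Damaging	0.999	Damaging	-6.49	Damaging	Yes
VCP	7415	P137L	Yes	0.4	Neutral	1	Damaging	-9.31	Damaging	Yes
VCP	7415	R155G	Yes	0.4	Neutral	0.998	Damaging	-5.18	Damaging	No
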