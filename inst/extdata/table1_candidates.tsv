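proband	sex	gene	transcript	hgvs_c	hgvs_p	effect	af_gnomad	cadd_phred	clinvar	acmg	inheritance
P1	male	MTMR8	NM_017677	c.T709C	p.Y237H	nonsynonymous	.	23.7	.	VUS (PP3,PM2,BP1)	x_linked_recessive
P2	male	KIF18A	NM_031217	c.C1014G	p.F338L	nonsynonymous	.	24	.	Likely Benign (BP1,BP4,PM2)	de_novo
P3	male	DDX60	NM_017631	c.C2269G	p.P757A	nonsynonymous	.	22.8	.	Likely Benign (BP1,BP4,PM2)	autosomal_recessive
P3	male	RASSF3	NM_178169	c.C82A	p.P28T	nonsynonymous	.	22.9	.	VUS (PM2,BP4)	de_novo
P3	male	ARHGAP4	NM_001164741	c.G771A	p.W257X	stopgain	.	23.5	.	Likely Pathogenic (PVS1,PM2)	x_linked_recessive
P3	male	EGFL6	NM_001167890	c.G1429T	p.G477W	nonsynonymous	.	33	.	Likely Benign (BP1,BP4,PM2)	x_linked_recessive
P3	male	RHBDD2	NM_001346187	c.C323T	p.P108L	nonsynonymous	0.00003	33	.	VUS (PM2,BP4)	autosomal_recessive
P3	male	TMEM154	NM_152680	c.G544T	p.E182X	stopgain	.	37	.	VUS (PM2)	de_novo
P4	male	GAB3	NM_001282283	c.C1249T	p.P417S	nonsynonymous	0.00001	24	.	Likely Benign (BP4,PM2)	x_linked_recessive
P4	male	ADGRG4	NM_153834	c.G8248A	p.G2750R	nonsynonymous	0.00005	34	.	Likely Benign (BP1,BP4,PM2)	x_linked_recessive
P5	male	DMD	NM_004009	c.C2815T	p.R939C	nonsynonymous	0.0001	29.2	conflicting	Benign (BS2,BP6,BP1)	x_linked_recessive
P6	male	DNAH3	NM_001347886	c.A11180G	p.Y3727C	nonsynonymous	.	22.2	.	Benign (BS1,BS2,BP4,BP1)	autosomal_recessive
P6	male	ADGRG4	NM_153834	c.A4477G	p.N1493D	nonsynonymous	0.0001	22.3	vus	Benign (BS1,BS2,BP4,BP1,BP3)	x_linked_recessive
P6	male	PCDH19	NM_020766	c.C762A	p.N254K	nonsynonymous	.	22.7	vus	VUS (PM1,PM2,BP4)	x_linked_recessive
P6	male	ABAT	NM_000663	c.C947T	p.A316V	nonsynonymous	0.00001	23.7	.	VUS (PM2,BP4)	autosomal_recessive
P6	male	MAP3K15	NM_001001671	c.G1591A	p.V531I	nonsynonymous	.	24.5	.	Likely Benign (BP1,BP4,PM2)	x_linked_recessive
P6	male	ARMCX2	NM_177949	c.C7T	p.R3C	nonsynonymous	.	32	.	Likely Benign (BP1,BP4,PM2)	x_linked_recessive
P6	male	NID1	NM_002508	c.C1166T	p.T389M	nonsynonymous	0.0007	32	.	Likely Benign (BP4,BP1,PM2)	autosomal_recessive
P7	female	USF2	NM_003367	c.C403T	p.P135S	nonsynonymous	0.0003	22.1	vus	Benign (BS1,BS2,BP4,BP1)	de_novo
P7	female	P2RY2	NM_002564	c.C364A	p.L122I	nonsynonymous	.	22.2	.	VUS (PM2,BP4)	autosomal_recessive
P7	female	POGLUT3	NM_001363502	c.C1042T	p.P348S	nonsynonymous	0.0002	22.3	vus	Likely Benign (BP4,PM2)	autosomal_recessive
P8	male	TBX22	NM_001303475	c.G782T	p.W261L	nonsynonymous	0.000005	22.6	.	Likely Benign (BP4,PM2)	x_linked_recessive
P9	male	EGFL6	NM_001167890	c.G1429T	p.G477W	nonsynonymous	.	33	.	Likely Benign (BP1,BP4,PM2)	x_linked_recessive
P10	female	SFRP5	NM_003015	c.C938T	p.A313V	nonsynonymous	0.0002	23.2	.	Likely Benign (BP1,BP4,PM2)	autosomal_recessive
P10	female	RADIL	NM_018059	c.G574A	p.A192T	nonsynonymous	0.0002	23.4	.	Likely Benign (BP1,BP4,PM2)	autosomal_recessive
P10	female	GBF1	NM_004193	c.C3026T	p.A1009V	nonsynonymous	0.0003	25.1	.	Benign (BS1,BS2,BP4,BP1)	autosomal_recessive
P10	female	MIS18BP1	NM_018353	c.G1033A	p.A345T	nonsynonymous	.	25.5	.	Likely Benign (BP4,PM2)	de_novo
P11	male	ARR3	NM_004312	c.C577T	p.P193S	nonsynonymous	0.0002	22.1	likely_benign	Benign (BS1,BS2,BP1,BP4,BP6)	x_linked_recessive
P11	male	MCF2	NM_001171878	c.G2216A	p.R739H	nonsynonymous	0.00001	22.1	.	VUS (PM2,PP3,BP1)	x_linked_recessive
P11	male	MAGEB2	NM_002364	c.A647G	p.N216S	nonsynonymous	0.000005	22.4	vus	Likely Benign (BP1,PB4,PM2)	x_linked_recessive
P11	male	ARAF	NM_001256196	c.G633C	p.Q211H	nonsynonymous	0.00001	23.8	.	VUS (PM1,PM2,BP4)	x_linked_recessive
P12	male	ARR3	NM_004312	c.C577T	p.P193S	nonsynonymous	0.0002	22.1	likely_benign	Benign (BS1,BS2,BP1,BP4,BP6)	x_linked_recessive
P12	male	MCF2	NM_001171878	c.G2216A	p.R739H	nonsynonymous	0.00001	22.1	.	VUS (PM2,PP3,BP1)	x_linked_recessive
P12	male	MAGEB2	NM_002364	c.A647G	p.N216S	nonsynonymous	0.000005	22.4	vus	Likely Benign (BP1,PB4,PM2)	x_linked_recessive
P12	male	ARAF	NM_001256196	c.G633C	p.Q211H	nonsynonymous	0.00001	23.8	.	VUS (PM1,PM2,BP4)	x_linked_recessive
P13	male	ZNF41	NM_001324147	c.G1082A	p.G361E	nonsynonymous	.	24.8	.	Likely Benign (BP1,PB4,PM2)	x_linked_recessive
P13	male	AHDC1	NM_001029882	c.C104A	p.P35H	nonsynonymous	.	25.2	.	Likely Benign (BP1,PB4,PM2)	de_novo
P14	male	SRPX	NM_001170752	c.G256A	p.D86N	nonsynonymous	0.0001	21.7	.	Benign (BS1,BS2,BP1,BP4)	x_linked_recessive
P14	male	OBSL1	NM_015311	c.C2770T	p.R924W	nonsynonymous	0.000008	22.1	.	Likely Benign (BP1,PB4,PM2)	de_novo
P15	male	MECP2	NM_001110792	c.G898A	p.V300M	nonsynonymous	0.00009	23.9	benign	Benign (BS2,BP4,BP6,PM1)	x_linked_recessive
P15	male	HS6ST2	NM_001077188	c.948-2A>G	.	splicing	0.00007	25.6	.	Likely Benign (BS1,BS2,PVS1)	x_linked_recessive
P16	male	LRRFIP1	NM_001137550	c.A575G	p.H192R	nonsynonymous	0.00004	22	.	Likely Benign (BP1,BP4,PM2)	autosomal_recessive
P16	male	DLX3	NM_005220	c.C376T	p.P126S	nonsynonymous	0.00002	22.9	vus	Likely Benign (BS2)	autosomal_recessive
P16	male	ZMYM3	NM_201599	c.G2219A	p.R740H	nonsynonymous	0.000005	34	vus	VUS (PP2,PM2,BP4)	x_linked_recessive
P17	male	SMARCA1	NM_001282874	c.C215T	p.A72V	nonsynonymous	0.00002	20.1	.	Benign (BS2,BP4,BP1)	x_linked_recessive
P17	male	SYTL4	NM_001370164	c.G962A	p.R321H	nonsynonymous	0.00003	34	.	Benign (BS1,BS2,BP4)	x_linked_recessive
P18	female	LSG1	NM_018385	c.G665A	p.R222Q	nonsynonymous	0.0003	20.9	.	Likely Benign (BP4,PM2)	autosomal_recessive
P18	female	NDC1	NM_001168551	c.T1504C	p.F502L	nonsynonymous	0.0006	21.8	.	Benign (BS1,BS2,BP4)	autosomal_recessive
P18	female	ABCC10	NM_001350518	c.A1957G	p.S653G	nonsynonymous	0.00007	22.3	.	Likely Benign (BP1,BP4,PM2)	autosomal_recessive
P18	female	TRERF1	NM_033502	c.G3415T	p.V1139L	nonsynonymous	0.000003	22.4	.	Likely Benign (BP1,BP4,PM2)	autosomal_recessive
P18	female	DCTD	NM_001351743	c.G528C	p.K176N	nonsynonymous	0.000008	22.9	vus	Likely Benign (BP4,PM2)	autosomal_recessive
P18	female	SLC4A5	NM_133478	c.1268+2T>C	.	splicing	.	25.8	.	Likely Pathogenic (PVS1,PM2)	autosomal_recessive
P19	male	APOOL	NM_198450	c.G190A	p.G64S	nonsynonymous	0.0003	23.4	.	Benign (BS1,BS2,BP3)	x_linked_recessive
P19	male	NAF1	NM_138386	c.G373A	p.D125N	nonsynonymous	0.0007	23.4	benign	Benign (BS1,BS2,BP1,BP4)	autosomal_recessive
P19	male	RHO	NM_000539	c.T182C	p.V61A	nonsynonymous	0.000003	23.6	.	VUS (PM1,PP3,PM2)	autosomal_recessive
P19	male	USH2A	NM_206933	c.C1898T	p.S633L	nonsynonymous	0.0002	24.2	conflicting	Likely Benign (BP4,PM1,PM2)	autosomal_recessive
P19	male	SHROOM2	NM_001649	c.C623T	p.S208L	nonsynonymous	0.00001	25	.	VUS (PM1,PM2)	x_linked_recessive
P20	male	USP9X	NM_001039591	c.A5567G	p.E1856G	nonsynonymous	.	23.1	.	Likely Benign (BP1,BP4,PM1,PM2)	x_linked_recessive
P20	male	PRRG1	NM_001173486	c.T36A	p.N12K	nonsynonymous	.	23.9	.	VUS (PM2,BP4)	x_linked_recessive
P20	male	DMD	NM_004013	c.G1565A	p.R522Q	nonsynonymous	0.0003	24	benign	Benign (BS2,BP1,BP4,BP6)	x_linked_recessive
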