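gene	transcript	hgvs_c	hgvs_p	effect	af_gnomad	clinvar	cadd_phred	patients	acmg	omim_inheritance
AP3B1	NM_003664	c.3023_3025del	p.1008_1009del	nonframeshift	0.009	benign	.	P4,P18	Benign (PM4,BA1,BP6)	AR
ATM	NM_001351834	c.C1810T	p.P604S	nonsynonymous	0.003	conflicting	24.5	P5,P13	Benign (BS1,BS2,BP4,BP6,BP1)	AR/AD
C6	NM_001115131	c.C62T	p.A21V	nonsynonymous	0	vus	21.3	P3,P5	Likely Benign (PM2,BP1,BP4)	AR
LY9	NM_002348	c.510_512del	p.170_171del	nonframeshift	.	.	.	P23	Benign (PM4,BS1,BS2,BP4)	AR
LY9	NM_002348	c.1052_1053del	p.H351fs	frameshift	0	risk_factor	.	P13	VUS (PM2)	AR
IFIH1	NM_022168	c.2016delA	p.T672fs	frameshift	0	conflicting	.	P11	VUS (PVS1,PM2,BP6)	AR/AD
DOCK8	NM_203447	c.C3022T	p.R1008W	nonsynonymous	0.001	benign	35	P23	Benign (PM2,BP6,BP4,BP1)	AR
PSTPIP1	NM_001321137	c.C877T	p.R293C	nonsynonymous	0	vus	34	P4	Likely Benign (PP3,PS3,BS2,BP1)	AD
ATM	NM_001351834	c.G1516T	p.G506C	nonsynonymous	0	conflicting	33	P24	Likely Benign (PM2,BP6,BP1,BP4)	AR/AD
ATM	NM_001351834	c.G3257A	p.R1086H	nonsynonymous	0	vus	31	P16	VUS (PM2,BP1)	AR/AD
NOD2	NM_001293557	c.G2641C	p.G881R	nonsynonymous	0.01	conflicting	29.9	P9	Benign (PP5,BS1,BS2,BP4,BS3,BP6)	AD
NLRP12	NM_001277129	c.C850T	p.R284X	stopgain	0	pathogenic	29.6	P8	Likely Benign (PVS1,PS3,BS1,BS2)	AD
IFIH1	NM_022168	c.2807+1G>A	.	splicing	0.007	conflicting	28.5	P20	Likely Benign (PVS1,PS3,BS2,BS3)	AR/AD
DOCK8	NM_203447	c.G2554A	p.V852M	nonsynonymous	0	vus	28.2	P16	Likely Benign (PM2,BP1,BP4)	AR
ATM	NM_001351834	c.G3449C	p.R1150T	nonsynonymous	0	conflicting	27.6	P19	Likely Benign (PM2,BP4,BP6,BP1)	AR/AD
RNASEL	NM_021133	c.G523T	p.A175S	nonsynonymous	0	.	27	P14	VUS (PP3,PM2,BP1)	AR/AD
DCLRE1C	NM_001033855	c.C251G	p.S84C	nonsynonymous	0	.	26.4	P9	Likely Benign (PM2,BP1,BP4)	AR
C6	NM_000065	c.2381+2T>C	.	splicing	0.002	conflicting	26.4	P21	Pathogenic (PVS1,PP5,PM2)	AR
LRBA	NM_001199282	c.T2466G	p.I822M	nonsynonymous	0.001	.	25.3	P15	Likely Benign (PM2,BP4,BP6,BP1)	AR
CR2	NM_001877	c.G1676A	p.G559E	nonsynonymous	0.001	conflicting	24.7	P13	Likely Benign (PM2,BP4,BP6,BP1)	AR
PSTPIP1	NM_001321137	c.C398T	p.T133M	nonsynonymous	0.002	conflicting	24.6	P17	Benign (BP6,BS1,BS2,BP4,BP1)	AD
LYST	NM_001301365	c.C5048T	p.A1683V	nonsynonymous	.	.	24.6	P13	VUS (PM2,PP3,BP1)	AR
UNC13D	NM_199242	c.T1039C	p.S347P	nonsynonymous	0	vus	24.3	P7	VUS (PM2)	AR
IRAK3	NM_001142523	c.A328G	p.I110V	nonsynonymous	0.001	.	24.2	P19	Likey Benign (PM2,BP4,BP1,BP6)	AR
TTC7A	NM_020458	c.G563T	p.R188L	nonsynonymous	0.003	benign	23.9	P15	Likely Benign (BS1,BS2,BP4,BP6,BP1)	AR
CR2	NM_001877	c.G2856C	p.Q952H	nonsynonymous	0.001	conflicting	23.8	P24	Benign (BS1,BS2,BP4,BP6,BP1)	AR
STING1	NM_001367258	c.G218T	p.G73V	nonsynonymous	0	conflicting	22.5	P18	Likely Benign (PM2,BP4)	AR/AD
DOCK8	NM_203447	c.C4346T	p.S1449L	nonsynonymous	0	conflicting	22.5	P18	Likely Benign (PM2,BP4,BP1,BP6)	AR
LYST	NM_001301365	c.A10510G	p.I3504V	nonsynonymous	.	.	22.2	P4	Likely Benign (PM2,BP4,BP1)	AR
LIG4	NM_002312	c.A303T	p.R101S	nonsynonymous	.	.	22	P12	Likely Benign (PM2,BP4)	AR
IFIH1	NM_022168	c.A1046G	p.K349R	nonsynonymous	0.003	benign	21.8	P15	Benign (BS1,BS2,BP4,BP6,BP1)	AR/AD
TTC7A	NM_020458	c.G2258A	p.R753Q	nonsynonymous	0.001	likely_benign	21.5	P3	Likely Benign (PM2,BP4,BP6,BP1)	AR
IRAK3	NM_001142523	c.T989C	p.M330T	nonsynonymous	0.001	.	20.8	P19	Likely Benign (PM2,BP4,BP1,BP6)	AR
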