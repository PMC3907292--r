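moiety	total	seed
CaM	10	CaM
Ng	20	Ng
AKAPc	0.02	AKAPc
PP2B	4	PP2B
AKAP	6	AKAP
PP2A72	1	PP2A72
PP2A56	2	PP2A56
CDK5	2	CDK5
p35	2	p35
PKAr	1.2	PKA
PKAc	2.4	PKAc
PP1	2	PP1
D32	50	D32
AC5	2.5	AC5
PDE1	4	PDE1
PDE4	2	PDE4
PDE10	1	PDE10
D1R	1	D1R
Gbg	1	Golf
Gaolf	1	GaolfGDP_A
AncRA	0.2	AncRA
AncRN	1	AncRN
AncGA	1	AncGA
AncGN	0.18	AncGN
Fyn	2	Fyn
Csk	0.5	Csk
PAG	0.6	PAG
PTPa	0.5	PTPa
STEP	0.3	STEP
STEP2	0	STEP2
NMDAR	0.3	NMDARi
AP2	1	AP2
GRF	0.5	GRF
RAS	0.5	RASgdp
GAP	0.1	GAP
RAF	0.5	RAF
MEK	1.2	MEK
ERK	2	ERK
DUSP	1	DUSPi
GluR1	2	GluR1
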