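source	reaction_type	component	concentration_mM
Milligan1987	IVT	Tris-HCl	40
Milligan1987	IVT	MgCl2	15
Milligan1987	IVT	DTT	5
Milligan1987	IVT	Spermidine	2
Milligan1987	IVT	NTPs	4
Pokrovskaya1994	IVT	Tris-HCl	40
Pokrovskaya1994	IVT	MgCl2	6
Pokrovskaya1994	IVT	DTT	10
Pokrovskaya1994	IVT	Spermidine	2
Pokrovskaya1994	IVT	NTPs	2
Pokrovskaya1994	IVT	NaCl	10
Cunningham1991	IVT	Tris-HCl	40
Cunningham1991	IVT	MgCl2	12
Cunningham1991	IVT	DTT	5
Cunningham1991	IVT	Spermidine	4
Cunningham1991	IVT	NTPs	1
Cunningham1991	IVT	KCl	5
Gurevich1991	IVT	Tris-HCl	80
Gurevich1991	IVT	MgCl2	20
Gurevich1991	IVT	DTT	2
Gurevich1991	IVT	Spermidine	2.5
Gurevich1991	IVT	NTPs	7.5
Gurevich1991	IVT	Triton X-100	0.1
Sampson1988	IVT	Tris-HCl	34.2
Sampson1988	IVT	MgCl2	10
Sampson1988	IVT	DTT	1
Sampson1988	IVT	Spermidine	1
Sampson1988	IVT	NTPs	0.5
Wyatt1991	IVT	Tris-HCl	41.1
Wyatt1991	IVT	MgCl2	9.9
Wyatt1991	IVT	DTT	7.4
Wyatt1991	IVT	Spermidine	1.8
Wyatt1991	IVT	NTPs	2
NEB_HiScribe_manual	IVT	Tris-HCl	42
NEB_HiScribe_manual	IVT	MgCl2	25
NEB_HiScribe_manual	IVT	DTT	10
NEB_HiScribe_manual	IVT	Spermidine	2
NEB_HiScribe_manual	IVT	NTPs	10
NEB_HiScribe_manual	IVT	NaCl	50
Promega_manual	IVT	Tris-HCl	100
Promega_manual	IVT	MgCl2	9
Promega_manual	IVT	DTT	10
Promega_manual	IVT	Spermidine	1.5
Promega_manual	IVT	NTPs	2.5
ThermoFisher_manual	IVT	Tris-HCl	75
ThermoFisher_manual	IVT	MgCl2	8
ThermoFisher_manual	IVT	DTT	6
ThermoFisher_manual	IVT	Spermidine	1.6
ThermoFisher_manual	IVT	NTPs	1
ThermoFisher_manual	IVT	Tween-20	0.05
Sigma_manual	IVT	Tris-HCl	50
Sigma_manual	IVT	MgCl2	9
Sigma_manual	IVT	DTT	40
Sigma_manual	IVT	Spermidine	1.75
Sigma_manual	IVT	NTPs	1.5
Affymetrix_manual	IVT	Tris-HCl	30
Affymetrix_manual	IVT	MgCl2	4
Affymetrix_manual	IVT	DTT	20
Affymetrix_manual	IVT	Spermidine	1
Affymetrix_manual	IVT	NTPs	2
NEB_VCS_manual	capping	Tris	50
NEB_VCS_manual	capping	KCl	5
NEB_VCS_manual	capping	MgCl2	1
NEB_VCS_manual	capping	DTT	1
Hongene_manual	capping	Tris	50
Hongene_manual	capping	KCl	5
Hongene_manual	capping	MgCl2	1
Hongene_manual	capping	DTT	1
Fuchs2016	capping	Tris	50
Fuchs2016	capping	KCl	5
Fuchs2016	capping	MgCl2	1
Fuchs2016	capping	DTT	1
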