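network	method	fss_simple	fss_combined
amazon	bet	19928.94	21368.11
amazon	clo	18996.47	21317.18
amazon	deg	20892.47	21825.99
amazon	hc	21131.07	19646.13
amazon	iks	20041.84	18993.88
amazon	sc	19173.56	21600.94
amazon	tsa	18806.53	19728.44
amazon	vr	21176.56	19709.25
condmat	bet	7221.25	7311.28
condmat	clo	7221.54	7283.41
condmat	deg	7205.79	7307.24
condmat	hc	7205.75	7278.66
condmat	iks	7264.97	7336.69
condmat	sc	7221.5	7333.97
condmat	tsa	7197.31	7270.59
condmat	vr	7224.53	7284.29
dblp	bet	72673.86	73896.33
dblp	clo	72647.98	73863.33
dblp	deg	72679.94	74039.21
dblp	hc	72650.26	73661.48
dblp	iks	73038.16	74100.79
dblp	sc	72715.13	73680.69
dblp	tsa	72612.16	73735.09
dblp	vr	72753.74	73621.61
email_all	bet	36498.84	36852.86
email_all	clo	35627.5	36825.19
email_all	deg	36464.72	36863.84
email_all	hc	36500.04	36707.82
email_all	iks	36811.25	36845.56
email_all	sc	35647.38	36750.59
email_all	tsa	35597.56	36744.88
email_all	vr	36581.93	36672.45
email_core	bet	756.28	775.36
email_core	clo	755.08	774
email_core	deg	755.76	774.91
email_core	hc	755.74	775.35
email_core	iks	757.34	776.06
email_core	sc	757.19	772.16
email_core	tsa	758.44	776.5
email_core	vr	755.63	775.69
netsci	bet	66.75	70.28
netsci	clo	53.1	72.76
netsci	deg	70.38	74.21
netsci	hc	50.74	71.79
netsci	iks	63.94	71.13
netsci	sc	41.13	55.81
netsci	tsa	51.91	61.09
netsci	vr	76.04	76.06
pgp	bet	1401.24	1526.5
pgp	clo	1203.53	1533.98
pgp	deg	1242.64	1565.75
pgp	hc	1157.59	1562.12
pgp	iks	1392.66	1504.31
pgp	sc	1147.16	1529.56
pgp	tsa	1154.72	1427.03
pgp	vr	1494	1557.41
usair	bet	155.04	154.19
usair	clo	153.75	153.87
usair	deg	151.42	154.78
usair	hc	152.47	157.49
usair	iks	150.78	153.72
usair	sc	151.63	157.22
usair	tsa	153.97	154.47
usair	vr	153.28	153.66
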