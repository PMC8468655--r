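network	fss
usair	156.1
netsci	76.4
email_core	776.85
pgp	1556.82
condmat	7316.78
email_all	36868.83
amazon	21857.31
dblp	74277.69
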