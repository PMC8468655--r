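network	n_nodes	n_edges	avg_degree	avg_path	clustering	ks_max	n_communities
usair	332	2126	12.807	2.738	0.749	26	7
netsci	379	914	4.82	6.042	0.798	8	18
email_core	1005	25571	50.88	2.586	0.399	56	41
pgp	10680	24316	4.55	7.463	0.44	31	117
condmat	23133	93497	8.51	5.352	0.633	25	62
email_all	265214	420045	3.03	4.118	0.486	39	115
amazon	262111	1234877	9.42	8.831	0.42	10	214
dblp	317080	1049866	6.62	6.792	0.632	113	573
youtube	1134890	2987624	5.27	5.279	0.08	51	9635
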