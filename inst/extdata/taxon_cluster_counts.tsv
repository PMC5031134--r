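level	taxon	n_genomes	method	core	pan	singletons
species	H_pylori	60	DAB_Pfam	724	1334	142
species	L_monocytogenes	26	DAB_Pfam	1333	2142	309
genus	Bacillus	60	DAB_Pfam	792	5984	1474
genus	Pseudomonas	60	DAB_Pfam	1113	6572	1554
genus	Streptococcus	60	DAB_Pfam	535	3435	845
family	Enterobacteriaceae	60	DAB_Pfam	146	6690	1664
order	Corynebacteriales	60	DAB_Pfam	475	6022	1719
phylum	Cyanobacteria	60	DAB_Pfam	400	9752	4428
species	H_pylori	60	DAB_InterPro	534	2888	853
species	L_monocytogenes	26	DAB_InterPro	1414	3415	847
genus	Bacillus	60	DAB_InterPro	342	16349	6745
genus	Pseudomonas	60	DAB_InterPro	646	19387	7444
genus	Streptococcus	60	DAB_InterPro	244	8265	3276
family	Enterobacteriaceae	60	DAB_InterPro	20	19590	8173
order	Corynebacteriales	60	DAB_InterPro	130	22558	10554
phylum	Cyanobacteria	60	DAB_InterPro	120	27421	16140
species	H_pylori	60	SB	1036	1503	295
species	L_monocytogenes	26	SB	2294	2937	746
genus	Bacillus	60	SB	885	9903	5505
genus	Pseudomonas	60	SB	1453	12204	4838
genus	Streptococcus	60	SB	716	4468	2116
family	Enterobacteriaceae	60	SB	197	10899	6715
order	Corynebacteriales	60	SB	605	12632	9087
phylum	Cyanobacteria	60	SB	511	10575	11154
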