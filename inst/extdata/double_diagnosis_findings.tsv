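fetus_id	phenotype_class	kind	genes	chrom	start	end	consequence	inheritance
FetalC0247	Facial	cnv	OR4M2,OR4N4,POTEB3,OR4N4C,POTEB	15	21422120	22429653	duplication	de_novo
FetalC0247	Facial	variant	STAG2	X	124062902	124062903	missense	x_linked_maternal
FetalC0290	Hydrops	cnv	TSC2,PKD1	16	2084905	2118880	deletion	de_novo
FetalC0290	Hydrops	variant	NIPBL	5	37007445	37007446	missense	de_novo
FetalC0309	Skeletal	cnv	FOXD4L6,SPATA31A6,CBWD6,CNTNAP3B	9	40992379	42569325	duplication	de_novo
FetalC0309	Skeletal	variant	KIF22	16	29802813	29802814	missense	de_novo
FetalC0450	Cardiac	cnv	DGCR6,PRODH,DGCR2,UFD1,CDC45,TBX1,COMT,ARVCF,DGCR8,RANBP1,ZDHHC8,CRKL,LZTR1,HIRA,GNB1L,TANGO2,MED15,PI4KA,TXNRD2,SNAP29,SCARF2,SERPIND1	22	18108288	21085716	deletion	de_novo
FetalC0450	Cardiac	variant	CHD4	12	6587859	6587860	missense	de_novo
FetalC0497	Cardiac	cnv	FOXD4L6,SPATA31A6,CBWD6,CNTNAP3B	9	41034878	42569325	duplication	de_novo
FetalC0497	Cardiac	variant	CHD7	8	60828661	60828662	splice_region	de_novo
FetalC0759	Skeletal	cnv	OR4M2,OR4N4,POTEB3,OR4N4C,POTEB	15	21165579	22279173	duplication	de_novo
FetalC0759	Skeletal	variant	BBS5	2	169482248	169482249	splice_region	biparental_homozygous
FetalC0862	Cardiac	cnv	ADAMTS2	5	179343692	179345442	duplication	compound_heterozygous
FetalC0862	Cardiac	variant	ADAMTS2	5	179125137	179125138	missense	compound_heterozygous
FetalC1438	Hydrops	cnv	GTF2H2C,SERF1B,SMN2	5	69582366	70785650	deletion	de_novo
FetalC1438	Hydrops	variant	FLNB	3	58078804	58078805	missense	de_novo
FetalC1533	Skeletal	cnv	H3-2,PPIAL4E,FAM72C,NBPF15	1	143449487	144450895	deletion	de_novo
FetalC1533	Skeletal	variant	FGFR3	4	1804392	1804393	missense	de_novo
FetalC1595	Gastrointestinal tract and AW	cnv	CYP21A2	6	32013119	32044190	duplication	compound_heterozygous
FetalC1595	Gastrointestinal tract and AW	variant	CYP21A2	6	32038507	32038508	missense	compound_heterozygous
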