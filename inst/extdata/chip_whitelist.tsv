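kind	gene	hgvs_p	consequence	artifact_mode
site	DNMT3A	p.R882H	missense
site	DNMT3A	p.R882C	missense
site	DNMT3A	p.R736H	missense
site	DNMT3A	p.R729W	missense
site	JAK2	p.R683G	missense
site	SF3B1	p.G742D	missense
site	GNB1	p.I80T	missense
site	DNMT3A	p.R326C	missense
site	DNMT3A	p.W860R	missense
site	TET2	p.C1135Y	missense
site	TET2	p.C1193W	missense
site	JAK2	p.V617F	missense
site	SF3B1	p.K700E	missense
site	SF3B1	p.K666N	missense
site	SRSF2	p.P95H	missense
site	SRSF2	p.P95L	missense
site	GNB1	p.K57E	missense
site	GNAS	p.R201C	missense
site	GNAS	p.R844C	missense
site	CBL	p.C381Y	missense
site	CBL	p.R420Q	missense
site	TP53	p.R175H	missense
site	TP53	p.R248Q	missense
site	TP53	p.R273H	missense
site	TP53	p.P72R	missense
site	ASXL1	p.P815L	missense
exemption	TET2	p.H1904R	missense
exemption	TET2	p.I1873T	missense
exemption	TET2	p.T1884A	missense
rule	ASXL1		frameshift,nonsense,splice
rule	TET2		frameshift,nonsense,splice
rule	PPM1D		frameshift,nonsense,splice
rule	DNMT3A		frameshift,nonsense,splice
rule	TP53		frameshift,nonsense,splice
artifact	TP53	p.P72R		always
artifact	ASXL1	p.P815L		always
artifact	ASXL1	p.G646Wfs*12		low_vaf
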