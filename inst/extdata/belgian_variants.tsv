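variant_id	cdna_hgvs	protein_hgvs	polyphen2	sift	cadd	maf_gnomad_nfe	in_excluded_region	patient_carriers	control_carriers
L620P	c.1859T>C	p.L620P	1.000	0	31	0.055	FALSE	8	1
G826R	c.2476G>A	p.G826R	0.533	0.23	20.7	0.075	FALSE	5	4
A845V	c.2534C>T	p.A845V	1.000	0	25.2	NA	FALSE	1	0
R880Q	c.2639G>A	p.R880Q	0.999	0	28.7	0.198	FALSE	3	1
R989H	c.2966G>A	p.R989H	1.000	0	28.2	0.011	FALSE	1	0
G1731S	c.5191G>A	p.G1731S	1.000	0.01	26.5	0.0035	FALSE	2	0
G1820S	c.5458G>A	p.G1820S	0.994	0.03	32	0.046	FALSE	2	0
R1932C	c.5794C>T	p.R1932C	1.000	0	26.3	0.0047	FALSE	1	0
P1952R	c.5855C>G	p.P1952R	1.000	0	24.9	NA	FALSE	1	0
F2100S	c.6299T>C	p.F2100S	0.977	0	26.1	NA	FALSE	1	0
E188G	c.563A>G	p.E188G	0.244	0.46	13.13	47.4	FALSE	NA	NA
G215S	c.643G>A	p.G215S	0.029	0.92	0.100	6.34	FALSE	NA	NA
R1349Q	c.4046G>A	p.R1349Q	0.002	0.40	0.267	43.2	FALSE	NA	NA
G1527A	c.4580G>C	p.G1527A	0.000	0.89	3.349	83.0	FALSE	NA	NA
E167K	c.499G>A	p.E167K	NA	NA	15.48	NA	FALSE	1	0
A589G	c.1766C>G	p.A589G	NA	NA	0.123	NA	FALSE	1	0
A878T	c.2632G>A	p.A878T	NA	NA	16.32	NA	FALSE	1	0
R1453C	c.4357C>T	p.R1453C	NA	NA	23.3	NA	FALSE	2	0
splice_3148	c.3148-5C>T		NA	NA	0.103	NA	FALSE	2	0
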