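approach	chrom	pos	ref	alt	dbsnp_id	maf	gene	refseq	cdna	protein	consequence
A	5	156714137	G	A	rs2288068	0.093	CYFIP2	NM_001037333	c.207+20G>A	.	intronic
A	5	156727692	T	C	rs3815829	0.082	CYFIP2	NM_001037333	c.388-31T>C	.	intronic
A	5	156766037	A	G	rs3734027	0.465	CYFIP2	NM_001037333	c.2386-28A>G	.	intronic
A	5	156770209	G	A	rs10214194	0.229	FNDC9	NM_001001343	c.336C>T	p.S112=	synonymous
B	5	148808474	C	T	rs13158382	0.037	MIR143/145	NR_029684	c.-112C>T	.	upstream
B	5	149003532	C	A	.	.	ARHGEF37	NM_001001669	c.1336-43C>A	.	intronic
B	5	149776232	C	T	rs15251	0.219	TCOF1	NM_001135243	c.4169C>T	p.A1390V	missense
B	5	149776355	G	C	rs45491898	0.016	TCOF1	NM_001135243	c.4292G>C	p.G1431A	missense
B	5	149919778	G	A	rs61732050	0.041	NDST1	NM_001543	c.1701G>A	p.A567=	synonymous
B	5	149932712	G	A	rs62383060	0.001	NDST1	NM_001543	c.2530-63G>A	.	intronic
B	5	150578574	A	G	rs3734038	0.195	CCDC69	NM_015621	c.303T>C	p.N101=	synonymous
B	5	150603444	C	G	rs248461	0.295	CCDC69	NM_015621	c.-40487+40G>C	.	intronic
B	5	150666933	C	A	rs375396	0.218	SLC36A3	NM_001145017	c.705G>T	p.L235=	synonymous
B	5	151046928	C	T	rs729853	0.168	SPARC	NM_003118	c.585+100G>A	.	intronic
B	5	151054137	A	C	rs2116780	0.170	SPARC	NM_003118	c.120+36T>G	.	intronic
B	5	153783753	C	T	rs6580076	0.242	GALNT10	NM_198321	c.1146C>T	p.A382=	synonymous
B	5	154135386	G	A	rs78112077	0.054	LARP1	NM_015315	c.206-34499G>A	.	intronic
B	5	156816521	C	T	rs142867180	0.012	CYFIP2	NM_001037333	c.3446+86C>T	.	intronic
B	5	157158414	C	A	rs2270819	0.115	THG1L	NM_017872	c.-35C>A	.	five_prime_utr
B	5	157158439	C	A	rs2270818	0.115	THG1L	NM_017872	c.-10C>A	.	five_prime_utr
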