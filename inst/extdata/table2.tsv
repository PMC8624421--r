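patient	gene	cdna	type	dbsnp	class	gnomad_exome_af	gnomad_genome_af	misz	pli	fe	me
1	FMN2	c.162delC	FD		VUS	0.000000	0.000000	1.42	0.99	no	yes
1	YWHAE	c.G142A	M		VUS	0.000000	0.000000	3.25	0.96	yes	na
1	YWHAE	c.T116C	M		VUS	0.000000	0.000000	3.25	0.96	yes	na
1	PHAX	c.C379T	PS		VUS	0.000000	0.000000	-0.51	0.00	yes	na
1	POR	c.T1231C	M		VUS	0.000000	0.000000	-0.54	0.00	yes	na
2	DEPDC1	c.T1459A	M		VUS	0.000000	0.000000	-0.32	0.00	yes	na
4	F5	c.A1867G	M		VUS	0.000000	0.000000	-1.30	0.00	no	na
4	PHRF1	c.G1075A	M	rs551874512	VUS	0.000033	0.000032	-1.36	0.95	yes	na
4	MYBPC3	c.C482A	M		VUS	0.000000	0.000000	0.69	0.00	no	na
4	PACS1	c.G1069A	M	rs750459659	VUS	0.000041	0.000032	4.32	1.00	yes	na
4	OAS3	c.C1390T	M	rs750291946	VUS	0.000012	0.000000	-0.60	0.00	yes	na
4	MAN2A2	c.G478A	M	rs374688808	VUS	0.000012	0.000032	1.28	0.00	yes	yes
4	SNF8	c.G578A	M	rs775611332	VUS	0.000025	0.000000	0.97	0.29	yes	yes
4	MED15	c.C730A	M		VUS	0.000000	0.000000	2.50	0.96	yes	na
4	IQCF5	c.C283T	M	rs772101978	VUS	0.000100	0.000000	-1.59	0.43	no	na
4	TMEM165	c.C782A	M		VUS	0.000000	0.000000	1.83	0.94	yes	na
4	NOTCH4	c.G1118A	M	rs745883985	VUS	0.000033	0.000032	2.45	0.00	yes	na
4	DPPA5	c.G214A	M		VUS	0.000000	0.000000	1.64	0.00	no	na
4	SLC22A1	c.C523T	M	rs768905186	VUS	0.000004	0.000000	-0.28	0.00	no	na
4	MGAM2	c.G3015T	M		VUS	0.000000	0.000000			na	na
4	IKBKB	c.G809A	M	rs200841053	VUS	0.000024	0.000032	2.90	1.00	yes	na
5	PCDH15	c.G139A	M		VUS	0.000000	0.000000	-3.27	0.00	no	yes
5	ZNF592	c.C3433A	M		VUS	0.000000	0.000000	1.10	0.95	yes	na
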