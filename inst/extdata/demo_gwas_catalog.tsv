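SNPS	CHR_ID	CHR_POS	DISEASE/TRAIT	MAPPED_GENE	PUBMEDID
rs3731217	9	21984661	Acute lymphoblastic leukemia	CDKN2A	00000001
rs9999901	9	22000000	Glioma	CDKN2A-AS1	00000002
rs9999902	5	1290000	Bladder cancer	TERT	00000003
rs9999903	8	128750000	Breast cancer	MYC	00000004
rs9999904	8	129500000	Ovarian cancer	MYC	00000005
rs9999905	22	48100000	Endometrial cancer	FAM19A5	00000006
rs9999906	1	1000000	Height	AGRN	00000007
rs9999907; rs9999908	3	169400000	Bladder cancer	TERC	00000008
rs9999909	12	NR	CRC	KDM5A	00000009
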