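gene	snp_id	locus	n_heterozygotes	n_ai	k_risk	k_prot	printed_p	cohort
CDKN2A	rs3731217	chr9:21984661	50	17	11	6	0.17	current
IKZF1	rs4132601	chr7:50470604	142	29	17	12	0.23	current
CEBPE	rs2239633	chr14:23589057	42	32	19	13	0.19	current
ARID5B	rs7089424	chr10:63752159	61	35	20	15	0.25	current
PIP4K2A	rs10764338	chr10:22866892	19	9	4	5	0.5	current
GATA3	rs3824662	chr10:8104208	37	19	10	9	0.5	current
CDKN2A	rs3731249	chr9:21970916	17	17	14	3	0.006	prior
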