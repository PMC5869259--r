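gene_id	symbol	mean_pre	mean_post	p_value	synthetic
ENSBTAG00000043414	snoR38	1.415	6.750	0.005	no
ENSBTAG00000044882	Novel_gene_1	0.546	4.877	0.005	no
ENSBTAG00000011660	MSMB	4.309	7.658	0.005	no
ENSBTAG00000042447	SNORD49	4.599	0.457	0.005	no
ENSBTAG00000030124	Novel_gene_2	6.815	2.908	0.005	no
ENSBTAG00000008134	BDNF	5.890	2.022	0.005	no
ENSBTAG00000017502	RIMKLA	6.187	2.928	0.005	no
ENSBTAG00000045577	MCCD1	6.804	3.690	0.005	no
ENSBTAG00000004657	FBLL1	4.978	1.947	0.005	no
ENSBTAG00000033173	BHLHE22	6.871	3.865	0.010	no
SYNTH0000000000001	DISTRACT_FC_ONLY	1.000	4.500	0.020	yes
SYNTH0000000000002	DISTRACT_FC_ONLY2	7.200	3.900	0.049	yes
SYNTH0000000000003	DISTRACT_P_ONLY	2.000	4.900	0.001	yes
SYNTH0000000000004	DISTRACT_P_ONLY2	5.500	2.700	0.010	yes
SYNTH0000000000005	DISTRACT_WEAK	3.100	3.900	0.040	yes
SYNTH0000000000006	DISTRACT_BOUNDARY_P	2.000	5.100	0.011	yes
SYNTH0000000000007	DISTRACT_BOUNDARY_FC	1.000	3.999	0.005	yes
SYNTH0000000000008	DISTRACT_NULL	4.000	4.050	0.900	yes
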