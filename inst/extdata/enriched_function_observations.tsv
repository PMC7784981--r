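section	pfam_function	slug	n_present_resistant	n_present_nonpermissive	n_present_permissive	n_total_resistant	n_total_nonpermissive	n_total_permissive
resistant	Mur ligase family, glutamate ligase domain	mur_ligase	10	0	0	10	3	10
resistant	NADH:flavin oxidoreductase/NADH oxidase family	nadh_flavin_oxidoreductase	10	0	0	10	3	10
resistant	Thiamine pyrophosphokinase C terminal	thiamine_pyrophosphokinase	10	0	0	10	3	10
resistant	Amidinotransferase ArcA	amidinotransferase_arca	10	0	0	10	3	10
resistant	Bacitracin resistance protein BacA	bacitracin_resistance_baca	10	0	0	10	3	10
susceptible	Glycosyl transferase WecB/TagA/CpsF family	glycosyl_transferase_wecb	0	3	10	10	3	10
susceptible	C-terminal four TMM region of protein-O-mannosyltransferase	o_mannosyltransferase_tmm	0	3	10	10	3	10
susceptible	Dehydrogenase E1 component	dehydrogenase_e1	0	3	10	10	3	10
susceptible	Cytidylate kinase	cytidylate_kinase	0	3	10	10	3	10
susceptible	Metallopeptidase family M81	metallopeptidase_m81	0	3	10	10	3	10
permissive	Acyl-CoA dehydrogenase, C-terminal domain	acyl_coa_dehydrogenase	2	1	10	10	3	10
permissive	GlcNAc-PI de-N-acetylase	glcnac_pi_deacetylase	0	1	8	10	3	10
permissive	Family 4 glycosyl hydrolase C-terminal domain	glycosyl_hydrolase_family4	0	1	8	10	3	10
permissive	Butirosin biosynthesis protein H, N-terminal	butirosin_biosynthesis_h	0	0	7	10	3	10
permissive	Glycine zipper	glycine_zipper	0	0	7	10	3	10
nonpermissive	Phage terminase, small subunit	phage_terminase_small	1	3	0	10	3	10
nonpermissive	S-adenosylmethionine synthetase, N-terminal domain	sam_synthetase_n	0	2	0	10	3	10
nonpermissive	Domain of unknown function (DUF4391)	duf4391	1	3	1	10	3	10
nonpermissive	Pectate lyase superfamily protein	pectate_lyase	1	3	2	10	3	10
nonpermissive	HsdM N-terminal domain	hsdm_n_terminal	0	2	1	10	3	10
nonpermissive_resistant	RmuC family	rmuc_family	9	3	1	10	3	10
nonpermissive_resistant	Cytidine triphosphate (CTP) synthase	ctp_synthase	5	3	0	10	3	10
nonpermissive_resistant	TPM domain	tpm_domain	10	3	4	10	3	10
nonpermissive_resistant	MafB19-like deaminase	mafb19_deaminase	10	3	4	10	3	10
nonpermissive_resistant	Tetracyclin repressor-like, C-terminal domain	tetracyclin_repressor_c	10	3	4	10	3	10
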