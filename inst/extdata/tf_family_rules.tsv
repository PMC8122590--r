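pfam_accession	domain_name	family	superfamily	evalue_threshold	is_dbd
PF05110	AF-4	AF-4		NA	1
PF01388	ARID	ARID		NA	1
PF09270	BTD	BTD		NA	1
PF00170	bZIP_1	bZIP_1	bZIP	NA	1
PF07716	bZIP_2	bZIP_2	bZIP	NA	1
PF03131	bZIP_Maf	bZIP_1	bZIP	NA	1
PF02312	CBF_beta	CBF_beta		NA	1
PF02045	CBFB_NFYA	CBFB_NFYA	NF-Y	NA	1
PF00808	CBFD_NFYB_HMF	CBFD_NFYB_HMF	NF-Y	NA	1
PF03859	CG-1	CG-1		NA	1
PF04516	CP2	CP2		NA	1
PF00313	CSD	CSD		NA	1
PF16019	CSRNP_N	CSRNP_N		NA	1
PF00859	CTF_NFI	CTF_NFI	MH1	NA	1
PF03165	MH1	MH1	MH1	NA	1
PF02319	E2F_TDP	E2F_TDP		NA	1
PF00178	Ets	Ets	ETS	NA	1
PF04621	ETS_PEA3_N	ETS_PEA3_N	ETS	NA	1
PF00250	Forkhead	Forkhead box		NA	1
PF08430	Forkhead_N	Forkhead box		NA	1
PF07842	GCFC	GCFC		NA	1
PF03615	GCM	GCM		NA	1
PF02946	GTF2I	GTF2I		NA	1
PF00010	HLH	bHLH	bHLH	1e-2	1
PF01056	Myc_N	Myc_N	bHLH	NA	1
PF11717	SIM_C	SIM_C	bHLH	NA	1
PF00505	HMG_box	HMG_box		1e-3	1
PF09011	HMG_box_2	HMG_box		1e-3	1
PF00046	Homeodomain	Homeodomain	Homeobox	1e-3	1
PF05920	Homeobox_KN	Homeodomain	Homeobox	1e-3	1
PF02376	CUT	CUT	Homeobox	NA	1
PF03792	PBC	PBC	Homeobox	NA	1
PF00157	Pou	Pou	Homeobox	NA	1
PF05044	HPD	HPD		NA	1
PF00447	HSF_DNA-binding	HSF_DNA-binding		NA	1
PF05225	HTH_psq	HTH_psq		NA	1
PF00605	IRF	IRF	IRF	NA	1
PF10401	IRF-3	IRF-3	IRF	NA	1
PF09271	LAG1-DNAbinding	LAG1-DNAbinding		NA	1
PF09738	LRRFIP	LRRFIP		NA	1
PF01429	MBD	MBD		NA	1
PF00249	Myb_DNA-binding	Myb_DNA-binding		NA	1
PF13921	Myb_DNA-bind_6	Myb_DNA-binding		NA	1
PF15065	NCU-G1	NCU-G1		NA	1
PF05224	NDT80_PhoG	NDT80_PhoG		NA	1
PF10491	Nrf1_DNA-binding	Nrf1_DNA-binding		NA	1
PF00870	P53	P53		NA	1
PF00292	PAX	PAX		NA	1
PF02229	PC4	PC4		NA	1
PF02257	RFX_DNA_binding	RFX_DNA_binding		NA	1
PF00554	RHD_DNA_binding	RHD_DNA_binding		NA	1
PF00853	Runt	Runt		NA	1
PF01342	SAND	SAND		NA	1
PF00319	SRF-TF	SRF-TF		NA	1
PF01017	STAT_alpha	STAT_alpha	STAT	NA	1
PF02864	STAT_binding	STAT_binding	STAT	NA	1
PF02865	STAT_int	STAT_int	STAT	NA	1
PF07531	TAFH	TAFH		NA	1
PF00907	T-box	T-box		NA	1
PF01285	TEA	TEA		NA	1
PF03299	TF_AP-2	TF_AP-2		NA	1
PF03529	TF_Otx	TF_Otx		NA	1
PF01833	TIG	TIG		NA	1
PF01166	TSC22	TSC22		NA	1
PF01167	Tub	Tub		NA	1
PF06546	Vert_HS_TF	Vert_HS_TF		NA	1
PF05485	THAP	THAP	zinc finger	NA	1
PF00320	GATA	GATA	zinc finger	NA	1
PF00751	DM	DM	zinc finger	NA	1
PF00104	Hormone_recep	Hormone_receptor	Nuclear Receptor	NA	1
PF02166	Androgen_recep	Androgen_receptor	Nuclear Receptor	NA	1
PF02159	Oest_recep	Oest_receptor	Nuclear Receptor	NA	1
PF02161	Prog_receptor	Prog_receptor	Nuclear Receptor	NA	1
PF02155	GCR	GCR	Nuclear Receptor	NA	1
PF00105	zf-C4	zf-C4	Nuclear Receptor	NA	1
PF02892	zf-BED	zf-BED	zinc finger	1e-3	1
PF00096	zf-C2H2	zf-C2H2	zinc finger	1e-3	1
PF13465	zf-H2C2_2	zf-C2H2	zinc finger	1e-3	1
PF13912	zf-C2H2_6	zf-C2H2	zinc finger	1e-3	1
PF12874	zf-met	zf-C2H2	zinc finger	1e-3	1
PF00642	zf-CCCH	zf-CCCH	zinc finger	1e-20	1
PF01530	zf-C2HC	zf-C2HC	zinc finger	NA	1
PF10601	zf-LITAF-like	zf-LITAF-like	zinc finger	NA	1
PF02891	zf-MIZ	zf-MIZ	zinc finger	NA	1
PF01422	zf-NF-X1	zf-NF-X1	zinc finger	NA	1
PF00651	BTB	BTB		NA	0
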