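accession	bin	description	mean_pc	mean_phs	mean_pec	mean_pehs
Solyc10g051390	RNA.RNA binding	RNA-binding glycine-rich protein-1b	2.8	0.1	2.3	0.6
Solyc02g068740	PS.photorespiration.glycine cleavage.H protein	Glycine cleavage system H protein 1	1.6	0.1	0.7	0.4
Solyc02g068450	transport.p- and v-ATPases.H+-transporting two-sector ATPase	Vacuolar ATPase F subunit	1.5	0.1	0.5	1.0
Solyc10g078960	protein.synthesis.ribosomal protein.eukaryotic.60S subunit.L21	60S ribosomal protein L21-like protein	1.3	0.1	1.3	1.0
Solyc09g090590	development.unspecified	Calcium binding protein caleosin	1.2	0.1	0.7	0.3
Solyc09g091170	not assigned.unknown	NADH dehydrogenase 1 alpha subcomplex subunit 13	1.2	0.1	1.5	0.1
Solyc07g005560	protein.synthesis.initiation	Eukaryotic translation initiation factor 5A	1.1	0.1	0.8	0.1
Solyc06g069860	protein.synthesis.ribosomal protein.eukaryotic.60S subunit.L34	60S ribosomal protein L34	1.1	0.1	0.1	0.5
Solyc10g007700	signaling.G-proteins	Ras-related protein Rab-2-A	1.0	0.1	0.6	0.9
Solyc02g070310	protein.synthesis.ribosomal protein.eukaryotic.60S subunit.L32	Ribosomal protein L32	0.9	0.1	0.5	0.5
Solyc09g007180	nucleotide metabolism.phosphotransfer and pyrophosphatases.adenylate kinase	Adenylate kinase	0.7	0.1	0.1	0.1
Solyc04g074550	mitochondrial electron transport.cytochrome c oxidase	Cytochrome c oxidase subunit Vib	0.7	0.1	0.1	0.9
Solyc05g005160	TCA.atp-citrate lyase	ATP-citrate lyase A-2	0.6	0.1	0.8	0.6
Solyc10g018060	not assigned.unknown	Elicitor-responsive protein 3	0.6	0.1	0.1	0.3
Solyc09g061230	redox.ascorbate and glutathione	Cytochrome b5	2.5	0.4	0.9	2.1
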