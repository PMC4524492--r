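taxon_id	display_name	accession	clade	at_percent	genome_length	ir_length	lsc_length	ssc_length	gene_count	introns_gI	introns_gII	repeat_percent	ir_present	ir_rdna	complete
Marsupiomonas_sp_NIES_1824	Marsupiomonas sp. NIES 1824	KM462870	Pedinophyceae	59.7	94262	9926	68185	6225	106	0	0	0.3	TRUE	TRUE	TRUE
Pedinomonas_tuberculata	Pedinomonas tuberculata	KM462867	Pedinophyceae	66.6	126694	16074	86619	7927	107	5	5	2.1	TRUE	TRUE	TRUE
Pedinomonas_minor	Pedinomonas minor	NC_016733	Pedinophyceae	65.2	98340	10639	70398	6664	106	0	0	0	TRUE	TRUE	TRUE
Dicloster_acuatus	Dicloster acuatus	KM462885	Chlorellales	70.0	169201	22061	87535	37544	112	6	0	5.4	TRUE	TRUE	TRUE
Parachlorella_kessleri	Parachlorella kessleri	NC_012978	Chlorellales	70.0	123994	10913	88297	13871	112	1	0	4.0	TRUE	TRUE	TRUE
Pseudochloris_wilhelmii	Pseudochloris wilhelmii	KM462886	Chlorellales	63.3	109775	12798	66211	17968	113	1	0	4.2	TRUE	TRUE	TRUE
Marvania_geminata	Marvania geminata	KM462888	Chlorellales	61.8	108470	NA	NA	NA	113	1	0	3.0	FALSE	FALSE	TRUE
Chlorella_vulgaris	Chlorella vulgaris	NC_001865	Chlorellales	68.4	150613	NA	NA	NA	113	3	0	7.3	FALSE	FALSE	TRUE
Chlorella_variabilis	Chlorella variabilis	NC_015359	Chlorellales	65.9	124579	NA	NA	NA	113	3	0	2.4	FALSE	FALSE	TRUE
Koliella_corcontica	"Koliella" corcontica	KM462874	Geminella	72.0	117543	15891	77346	8415	105	8	0	11.6	TRUE	TRUE	TRUE
Geminella_terricola	Geminella terricola	KM462881	Geminella	67.3	187843	18786	139317	10954	109	1	1	22.7	TRUE	TRUE	TRUE
Geminella_minor	Geminella minor	KM462883	Geminella	72.1	129187	11970	95317	9930	108	1	0	13.2	TRUE	TRUE	TRUE
Gloeotilopsis_sterilis	Gloeotilopsis sterilis	KM462877	Geminella	70.5	132626	13730	95069	10097	109	2	0	15.1	TRUE	TRUE	TRUE
Oocystis_solitaria	Oocystis solitaria	FJ968739	Oocystis	71.0	96287	NA	71295	NA	110	1	0	10.7	TRUE	TRUE	FALSE
Planctonema_lauterbornii	Planctonema lauterbornii	KM462880	Oocystis	66.8	114128	10577	81906	11068	111	1	0	7.3	TRUE	TRUE	TRUE
Pleurastrosarcina_brevispinosa	Pleurastrosarcina brevispinosa	KM462875	Pleurastrosarcina	65.5	295314	45468	194027	10351	111	16	3	21.3	TRUE	TRUE	FALSE
Neocystis_brevis	Neocystis brevis	KM462873	Prasiolales	68.6	211747	NA	NA	NA	112	5	0	19.8	FALSE	FALSE	TRUE
Stichococcus_bacillaris	Stichococcus bacillaris	KM462864	Prasiolales	68.1	116952	8272	51357	49051	107	4	0	14.3	TRUE	FALSE	TRUE
Prasiolopsis_sp_SAG_84_81	Prasiolopsis sp. SAG 84.81	KM462862	Prasiolales	64.9	306152	NA	NA	NA	108	7	1	23.1	FALSE	FALSE	TRUE
Chlorella_mirabilis	"Chlorella" mirabilis	KM462865	Prasiolales	68.5	167972	6835	121087	33215	110	0	0	5.5	TRUE	TRUE	TRUE
Koliella_longiseta	Koliella longiseta	KM462868	Prasiolales	68.6	197094	10619	141677	34179	111	0	0	4.0	TRUE	TRUE	TRUE
Pabia_signiensis	Pabia signiensis	KM462866	Prasiolales	66.6	236463	27336	141652	40139	111	1	0	20.0	TRUE	TRUE	TRUE
Parietochloris_pseudoalveolaris	Parietochloris pseudoalveolaris	KM462869	Parietochloris	68.4	145947	6786	115976	16399	109	0	0	6.8	TRUE	TRUE	TRUE
Leptosira_terrestris	Leptosira terrestris	NC_009681	Leptosira	72.7	195081	NA	NA	NA	107	4	0	4.8	FALSE	FALSE	TRUE
Xylochloris_irregularis	Xylochloris irregularis	KM462872	Xylochloris	60.3	181542	28473	76371	48225	110	1	5	7.1	TRUE	TRUE	TRUE
Microthamnion_kuetzingianum	Microthamnion kuetzingianum	KM462876	Microthamniales	65.3	158609	NA	NA	NA	107	1	0	6.7	FALSE	FALSE	TRUE
Fusochloris_perforata	Fusochloris perforata	KM462882	Microthamniales	64.9	148459	NA	NA	NA	107	0	0	3.5	FALSE	FALSE	TRUE
Trebouxia_aggregata	Trebouxia aggregata	EU123962-EU124002	Trebouxiales	65.2	245724	NA	NA	NA	100	8	0	42.7	FALSE	FALSE	FALSE
Myrmecia_israelensis	Myrmecia israelensis	KM462861	Trebouxiales	69.6	146596	NA	NA	NA	112	0	0	3.6	FALSE	FALSE	TRUE
Lobosphaera_incisa	Lobosphaera incisa	KM462871	Lobosphaera	72.2	156031	NA	NA	NA	111	1	0	11.4	FALSE	FALSE	TRUE
Dictyochloropsis_reticulata	Dictyochloropsis reticulata	KM462860	Watanabea	64.1	289394	NA	NA	NA	111	3	5	19.7	FALSE	FALSE	TRUE
Watanabea_reniformis	Watanabea reniformis	KM462863	Watanabea	58.8	201425	NA	NA	NA	110	6	1	23.0	FALSE	FALSE	TRUE
Choricystis_minor	Choricystis minor	KM462878	Choricystis	54.6	94206	NA	NA	NA	111	0	0	0	FALSE	FALSE	TRUE
Botryococcus_braunii	Botryococcus braunii	KM462884	Choricystis	57.6	172826	NA	NA	NA	112	1	2	9.8	FALSE	FALSE	TRUE
Elliptochloris_bilobata	Elliptochloris bilobata	KM462887	Elliptochloris	54.2	134677	NA	NA	NA	110	3	0	15.1	FALSE	FALSE	TRUE
Trebouxiophyceae_sp_MX_AZ01	Trebouxiophyceae sp. MX-AZ01	NC_018569	Elliptochloris	42.3	149707	NA	NA	NA	114	4	0	0.9	FALSE	FALSE	TRUE
Coccomyxa_subellipsoidea	Coccomyxa subellipsoidea	NC_015084	Elliptochloris	49.2	175731	NA	NA	NA	114	1	0	10.6	FALSE	FALSE	TRUE
Paradoxia_multiseta	Paradoxia multiseta	KM462879	Elliptochloris	49.4	183394	NA	NA	NA	114	1	4	18.6	FALSE	FALSE	TRUE
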