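((Marsupiomonas_sp_NIES_1824,(Pedinomonas_tuberculata,Pedinomonas_minor))Pedinophyceae,(((Chlorella_vulgaris,Chlorella_variabilis),((Marvania_geminata,Pseudochloris_wilhelmii),(Parachlorella_kessleri,Dicloster_acuatus)))Chlorellales,(((Oocystis_solitaria,Planctonema_lauterbornii)Oocystis,(Koliella_corcontica,(Gloeotilopsis_sterilis,(Geminella_terricola,Geminella_minor)))Geminella)GeminellaOocystis,(Pleurastrosarcina_brevispinosa,((Neocystis_brevis,((Prasiolopsis_sp_SAG_84_81,Stichococcus_bacillaris),(Chlorella_mirabilis,(Pabia_signiensis,Koliella_longiseta))))Prasiolales,(Parietochloris_pseudoalveolaris,((Leptosira_terrestris,(Xylochloris_irregularis,(Microthamnion_kuetzingianum,Fusochloris_perforata)Microthamniales))MicrothamnialesXylochloris,((((Trebouxia_aggregata,Myrmecia_israelensis)Trebouxiales,Lobosphaera_incisa),((Dictyochloropsis_reticulata,Watanabea_reniformis)Watanabea,((Choricystis_minor,Botryococcus_braunii)Choricystis,(Elliptochloris_bilobata,Coccomyxa_subellipsoidea,Trebouxiophyceae_sp_MX_AZ01,Paradoxia_multiseta)Elliptochloris))))Superclade))))CoreAfterGeminellaOocystis)CoreTrebouxiophyceae)ChlorellalesPlusCore)Root;
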