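file	md5	note
ancestral_sides.tsv	283c8bb0a653f52c08efd2efdb951765	
core91.txt	a5314b0d73de0ebce2e61d106c3ab7e8	
gene_synonyms.tsv	13128c37c4c39e0b17903c84b110dc02	
study_tree.nwk	c39f6131008992d2f7e9b07fc0f5f275	topology transcribed from the study figure and running text; Elliptochloris-clade internal resolution and some shallow placements stored as polytomies/best-supported arrangement
table1.tsv	52da3e8ba06ee76aac29b236ed62d715	intron GI/GII columns are best-effort (undelimited in source); lengths, A+T, gene counts, repeat percents validated against running text
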