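# Published per-age-group means for human paralog duplication classes
# (ENCODE 2011 Tfbs counts, FANTOM5 tissue BoE). Each group excludes
# duplications mapping to taxa of preceding (younger) groups.
group	mean_boe	sd_boe	n_boe	mean_tfbs	sd_tfbs	n_tfbs
Primate	0.09	0.22	2359	3.66	6.86	2034
Mammalian	0.14	0.27	3783	4.81	7.51	3647
Vertebrate	0.28	0.32	14518	6.60	8.13	14322
Animal	0.24	0.31	12329	6.02	7.74	12124
Eukaryotic	0.35	0.36	1757	10.02	9.43	1728
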