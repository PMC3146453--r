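sample	n_heterozygous	n_fixed	n_genotyped_bases	dbsnp_position_matches	dbsnp_allele_mismatches
bison	2426	8635	2447500	483	10
zebu	3890	1634	2395651	594	4
taurine	2525	1329	2306566	545	1
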