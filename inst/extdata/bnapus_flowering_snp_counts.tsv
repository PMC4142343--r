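# High-quality SNP class counts (min read depth 10) for the four-morphotype
# B. napus diversity panel, with panel-wide distinct-site totals and the
# captured target size.
genotype	total_hom	total_het	target_hom	target_het	panel_total_sites	panel_target_sites	target_length_bp
winter_osr_25629_3	2772	5259	546	1145	17316	4269	614000
fodder_silona	3974	4116	990	599	17316	4269	614000
spring_campino	4730	4283	1351	813	17316	4269	614000
swede_magres_pajberg	5849	4836	1538	771	17316	4269	614000
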