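quantity	value
n_fragments_total	1366
n_fragments_in_consensus	726
n_consensus_classes_reported_a	16
n_consensus_classes_reported_b	17
n_haplotypes_reported_a	74
n_haplotypes_reported_b	75
pairwise_shared_haplotypes_So_Sr	15
pairwise_shared_haplotypes_So_Ss	4
pairwise_shared_haplotypes_Sr_Ss	6
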