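key	value
total_snps	55465
transitions	36156
transversions	19309
shared_multi_genotype	9037
genic_snps	13367
cds_snps	4515
self_mismatch_sites	6072
reference_assembly_bp	318000000
estimated_genome_bp	370000000
validated_snps	4706
non_validated_snps	157
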