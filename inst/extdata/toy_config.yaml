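seed: 42
n_lines: 12
n_backcrosses: 1
n_selfing_generations: 4
n_sites: 120
n_chrom: 2
chrom_length_bp: 3.0e+07
chrom_length_cM: 150.0
mean_depth: 10.0
depth_dispersion: 2.0
base_error_rate: 0.005
site_dropout_rate: 0.1
quality_of_good_base: 30
min_site_reads: 3
hom_min_major_reads: 3
hom_min_base_quality: 20
het_min_reads_per_allele: 2
het_min_allele_fraction: 0.2
het_min_two_allele_fraction: 0.9
discovery_min_reads: 5
discovery_min_sample_fraction: 0.5
max_missing_initial: 0.8
required_allele_number: 2
min_genotype_classes: 2
min_maf: 0.1
max_site_heterozygosity: 0.1
max_missing_lmd: 0.5
window_snps: 10
step_snps: 5
sweep_k_sd: 3.0
min_shared: 30
n_groups: 2
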