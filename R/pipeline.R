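#' Run the full SNP-typing pipeline on a simulated panel
#'
#' End-to-end driver used by the bundled command-line script and the worked
#' examples: simulate a breeding panel and its read counts, call genotypes,
#' apply the filter cascade (LMD50), classify against the parent key, run the
#' window scan and sweep flagging, emit segments, and build the
#' neighbor-joining tree. All outputs are plain-text files under `out_dir`.
#'
#' The recurrent and donor parent are genotyped alongside the lines (samples
#' `RP` and `DP`), mirroring the usual design where parents are sequenced in
#' the same batch; the parent key is derived from their called genotypes.
#'
#' @param cfg configuration list from [read_run_config()] (or the defaults)
#' @param out_dir output directory (created if needed)
#' @return invisibly, a list with the main in-memory objects (`panel`,
#'   `cube`, `calls`, `filtered`, `classified`, `scan`, `sweeps`, `tree`,
#'   `groups`)
#' @export
run_pipeline <- function(cfg = run_config_defaults(), out_dir = tempdir()) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(cfg$seed)
  map <- random_genome_map(n_sites = cfg$n_sites, n_chrom = cfg$n_chrom,
                           length_bp = cfg$chrom_length_bp,
                           length_cM = cfg$chrom_length_cM)
  scheme <- breeding_scheme(n_lines = cfg$n_lines,
                            n_backcrosses = cfg$n_backcrosses,
                            n_selfing_generations = cfg$n_selfing_generations)
  panel <- simulate_panel(scheme, map)
  # append the two parents as samples
  ns <- n_sites(map)
  geno <- rbind(panel$geno, RP = rep(0L, ns), DP = rep(2L, ns))
  hap <- rbind(panel$hap1, RP = rep(0L, ns), DP = rep(1L, ns))
  full <- structure(list(geno = geno, hap1 = hap, hap2 = hap, map = map,
                         line_ids = rownames(geno),
                         donor = c(panel$donor, "RP", "DP"),
                         generation = panel$generation),
                    class = "truth_panel")
  model <- read_model(mean_depth = cfg$mean_depth,
                      depth_dispersion = cfg$depth_dispersion,
                      base_error_rate = cfg$base_error_rate,
                      site_dropout_rate = cfg$site_dropout_rate,
                      quality_of_good_base = cfg$quality_of_good_base)
  cube <- simulate_read_counts(full, model)
  ct <- call_thresholds(
    min_site_reads = cfg$min_site_reads,
    hom_min_major_reads = cfg$hom_min_major_reads,
    hom_min_base_quality = cfg$hom_min_base_quality,
    het_min_reads_per_allele = cfg$het_min_reads_per_allele,
    het_min_allele_fraction = cfg$het_min_allele_fraction,
    het_min_two_allele_fraction = cfg$het_min_two_allele_fraction,
    discovery_min_reads = cfg$discovery_min_reads,
    discovery_min_sample_fraction = cfg$discovery_min_sample_fraction)
  calls <- call_matrix(cube, ct)
  ft <- filter_thresholds(
    max_missing_initial = cfg$max_missing_initial,
    required_allele_number = cfg$required_allele_number,
    min_genotype_classes = cfg$min_genotype_classes,
    min_maf = cfg$min_maf,
    max_site_heterozygosity = cfg$max_site_heterozygosity,
    max_missing_lmd = cfg$max_missing_lmd)
  filt <- apply_cascade(calls, ft)
  key <- parent_key(filt$matrix, "RP", "DP")
  cm <- classify(filt$matrix, key)
  lines_only <- setdiff(cm$samples, c("RP", "DP"))
  cm_lines <- structure(list(codes = cm$codes[lines_only, , drop = FALSE],
                             sites = cm$sites, samples = lines_only,
                             non_parental = cm$non_parental),
                        class = "classified_matrix")
  comp <- sample_composition(cm_lines)
  track <- allele_frequency_track(cm_lines)
  scan <- window_scan(track, cfg$window_snps, cfg$step_snps)
  sweeps <- sweep_candidates(scan, cfg$sweep_k_sd)
  seg <- segments(cm_lines)
  dm <- snp_dissimilarity(filt$matrix, min_shared = cfg$min_shared)
  tree <- neighbor_joining(dm)
  groups <- extract_groups(tree, cfg$n_groups)

  p <- function(f) file.path(out_dir, f)
  write_counts_vcf(cube, p("counts.vcf"), map)
  write_genotype_tsv(filt$matrix, p("genotypes_lmd50.tsv"))
  utils::write.table(filt$attrition, p("filter_attrition.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(comp, p("sample_composition.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(track, p("allele_frequency_track.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(sweeps$windows, p("window_scan.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(sweeps$intervals, p("sweep_intervals.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  write_bed(seg, p("segments.bed"))
  ape::write.tree(tree, p("nj_tree.nwk"))
  utils::write.table(data.frame(sample = names(groups), group = groups),
                     p("groups.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  write_run_config(cfg, p("run_config.yaml"))
  invisible(list(panel = full, cube = cube, calls = calls, filtered = filt,
                 classified = cm_lines, composition = comp, track = track,
                 scan = scan, sweeps = sweeps, segments = seg, dist = dm,
                 tree = tree, groups = groups))
}
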