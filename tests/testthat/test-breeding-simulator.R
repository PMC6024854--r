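# Meiosis, pedigree and read-count simulator.

test_that("gamete from a homozygous parent reproduces the haplotype", {
  map <- toy_map()
  hom <- list(hap1 = rep(1L, n_sites(map)), hap2 = rep(1L, n_sites(map)))
  set.seed(1)
  expect_identical(simulate_gamete(hom, map), rep(1L, n_sites(map)))
})

test_that("zero genetic length means no recombination", {
  map <- toy_map(n_per_chrom = 8L, length_cM = 0)
  f1 <- list(hap1 = rep(0L, 8L), hap2 = rep(1L, 8L))
  set.seed(2)
  for (i in 1:20) {
    g <- simulate_gamete(f1, map)
    expect_true(all(g == 0L) || all(g == 1L))
  }
})

test_that("empty map errors", {
  map <- toy_map()
  map$sites <- map$sites[0, ]
  expect_error(simulate_gamete(list(hap1 = integer(0), hap2 = integer(0)),
                               map), "empty")
})

test_that("recombinant fraction between sites 10 cM apart matches Haldane", {
  # two sites 10 cM apart: c = (1 - exp(-0.2)) / 2
  chroms <- data.frame(chrom = "chr1", length_bp = 1e6, length_cM = 100)
  sites <- data.frame(chrom = "chr1", pos = c(1e5, 2e5),
                      rp_allele = "A", dp_allele = "G")
  map <- genome_map(chroms, sites)
  f1 <- list(hap1 = c(0L, 0L), hap2 = c(1L, 1L))
  set.seed(3)
  n <- 10000L
  rec <- vapply(seq_len(n), function(i) {
    g <- simulate_gamete(f1, map)
    g[1] != g[2]
  }, logical(1))
  c_hald <- (1 - exp(-0.2)) / 2
  se <- sqrt(c_hald * (1 - c_hald) / n)
  expect_lt(abs(mean(rec) - c_hald), 3 * se)
})

test_that("neutral BC1F5 panel recovers pedigree expectations", {
  set.seed(4)
  map <- random_genome_map(n_sites = 1000, n_chrom = 12)
  panel <- simulate_panel(breeding_scheme(n_lines = 500), map)
  # RP-allele frequency: one backcross gives expectation 0.75
  line_rp <- 1 - rowMeans(panel$geno) / 2
  se_rp <- stats::sd(line_rp) / sqrt(length(line_rp))
  expect_lt(abs(mean(line_rp) - 0.75), 3 * se_rp)
  # heterozygosity halves per selfing generation: 0.5 * (1/2)^4
  line_het <- rowMeans(panel$geno == 1L)
  se_het <- stats::sd(line_het) / sqrt(length(line_het))
  expect_lt(abs(mean(line_het) - 0.03125), 3 * se_het)
})

test_that("per-chromosome haplotypes are contiguous parental blocks", {
  set.seed(5)
  map <- random_genome_map(n_sites = 200, n_chrom = 2)
  panel <- simulate_panel(breeding_scheme(n_lines = 5), map)
  # expected switch count per haplotype ~ Poisson(cM/100) per meiosis;
  # 5 transitions deep, so runs must be few relative to sites
  for (l in 1:5) for (cc in unique(map$sites$chrom)) {
    h <- panel$hap1[l, map$sites$chrom == cc]
    expect_lt(length(rle(h)$lengths), 15)
  }
})

test_that("selection boosts the donor allele at the selected locus", {
  set.seed(6)
  map <- random_genome_map(n_sites = 200, n_chrom = 4)
  locus <- map$sites[97, ]
  sel <- data.frame(chrom = locus$chrom, pos = locus$pos,
                    mode = "require_donor_allele", rounds = 3L)
  panel <- simulate_panel(breeding_scheme(n_lines = 150, selection = sel),
                          map)
  dp_freq <- colMeans(panel$geno) / 2
  expect_gt(dp_freq[97], mean(dp_freq))
  expect_gt(dp_freq[97], 0.4)  # well above the neutral 0.25
})

test_that("unsatisfiable selection errors after the restart cap", {
  map <- toy_map()
  # donor homozygote cannot exist in a BC1 generation (selection applied at
  # every transition including the backcross)
  sel <- data.frame(chrom = "chr1", pos = 1e4,
                    mode = "require_donor_homozygote", rounds = 5L)
  set.seed(7)
  expect_error(
    simulate_panel(breeding_scheme(n_lines = 2, selection = sel,
                                   redraw_cap = 20L, line_restart_cap = 3L),
                   map),
    "unsatisfiable")
})

test_that("same seed gives identical panels and cubes", {
  map <- toy_map()
  p1 <- simulate_panel(breeding_scheme(n_lines = 10), map, seed = 11)
  p2 <- simulate_panel(breeding_scheme(n_lines = 10), map, seed = 11)
  expect_identical(p1$geno, p2$geno)
  c1 <- simulate_read_counts(p1, read_model(), seed = 12)
  c2 <- simulate_read_counts(p2, read_model(), seed = 12)
  expect_identical(c1$counts, c2$counts)
})

test_that("error-free reads reflect the true genotype exactly", {
  map <- toy_map()
  panel <- simulate_panel(breeding_scheme(n_lines = 4), map, seed = 13)
  cube <- simulate_read_counts(panel,
                               read_model(mean_depth = 10,
                                          base_error_rate = 0,
                                          site_dropout_rate = 0),
                               seed = 14)
  rp_idx <- match(map$sites$rp_allele, c("A", "C", "G", "T"))
  dp_idx <- match(map$sites$dp_allele, c("A", "C", "G", "T"))
  for (l in 1:4) for (s in seq_len(n_sites(map))) {
    cnt <- cube$counts[l, s, ]
    g <- panel$geno[l, s]
    if (g == 0L) expect_identical(sum(cnt[-rp_idx[s]]), 0L)
    if (g == 2L) expect_identical(sum(cnt[-dp_idx[s]]), 0L)
    if (g == 1L) expect_identical(sum(cnt[-c(rp_idx[s], dp_idx[s])]), 0L)
  }
})

test_that("counts sum to drawn depth and zero mean depth gives all missing", {
  map <- toy_map()
  panel <- simulate_panel(breeding_scheme(n_lines = 6), map, seed = 15)
  cube <- simulate_read_counts(panel, read_model(mean_depth = 8), seed = 16)
  expect_true(all(cube$counts >= 0))
  cube0 <- simulate_read_counts(panel, read_model(mean_depth = 0), seed = 17)
  expect_identical(sum(cube0$counts), 0L)
})

test_that("heterozygous truth yields balanced allele reads at depth 20", {
  chroms <- data.frame(chrom = "chr1", length_bp = 1e8, length_cM = 100)
  ns <- 10000L
  sites <- data.frame(chrom = "chr1", pos = seq_len(ns) * 100L,
                      rp_allele = "A", dp_allele = "G")
  map <- genome_map(chroms, sites)
  het <- structure(list(geno = matrix(1L, 1, ns,
                                      dimnames = list("H1", NULL)),
                        hap1 = matrix(0L, 1, ns), hap2 = matrix(1L, 1, ns),
                        map = map, line_ids = "H1", donor = "DP",
                        generation = "F1"),
                   class = "truth_panel")
  set.seed(18)
  cube <- simulate_read_counts(het,
                               read_model(mean_depth = 20,
                                          depth_dispersion = 1e9,
                                          base_error_rate = 0,
                                          site_dropout_rate = 0))
  frac_dp <- cube$counts[1, , "G"] / pmax(rowSums(cube$counts[1, , ]), 1)
  se <- stats::sd(frac_dp) / sqrt(ns)
  expect_lt(abs(mean(frac_dp) - 0.5), 3 * se)
})

test_that("multi-donor design panel has distinct donors and parent rows", {
  set.seed(19)
  map <- random_genome_map(n_sites = 220, n_chrom = 2)
  panel <- simulate_design_panel(map, n_donors = 4, n_lines_per_donor = 3)
  expect_identical(nrow(panel$geno), 4L * 3L + 5L)
  haps <- do.call(rbind, panel$donor_haps)
  expect_identical(nrow(unique(haps)), 4L)            # donors distinct
  expect_true(all(panel$geno["RP", ] == 0L))
  expect_identical(panel$geno["DP02", ],
                   stats::setNames(2L * panel$donor_haps[[2]],
                                   colnames(panel$geno)))
})

test_that("truth_genotype_matrix maps dosage onto map alleles", {
  map <- toy_map()
  panel <- simulate_panel(breeding_scheme(n_lines = 3), map, seed = 20)
  panel$geno[1, 1] <- 1L
  panel$geno[1, 2] <- 2L
  panel$geno[1, 3] <- 0L
  gm <- truth_genotype_matrix(panel)
  expect_identical(unname(gm$calls[1, 1:3]), c("A/G", "G/G", "A/A"))
  expect_false(anyNA(gm$calls))
})
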