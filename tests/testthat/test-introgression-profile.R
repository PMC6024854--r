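# Parent-key classification, composition, window scans, sweeps, segments.

test_that("classification against the parent key is definitional", {
  gm <- calls_matrix("A/A", "G/G", "A/G", "C/C", NA_character_)
  key <- data.frame(chrom = "chr1", pos = gm$sites$pos,
                    rp_allele = "A", dp_allele = "G", classifiable = TRUE)
  class(key) <- c("parent_key", "data.frame")
  cm <- classify(gm, key)
  expect_identical(unname(cm$codes[1, ]),
                   c("RP_HOM", "DP_HOM", "HET", "MISSING", "MISSING"))
  expect_identical(cm$non_parental, 1L)   # the C/C call
})

test_that("parent key requires both parents homozygous and different", {
  # samples in rows (S01 = RP, S02 = DP), sites in columns
  gm <- calls_matrix(c("A/A", "G/G", "A/A"),   # classifiable
                     c("A/A", "A/G", "A/A"),   # DP heterozygous
                     c("A/A", NA, "A/A"),      # DP missing
                     c("A/A", "A/A", "A/A"))   # parents identical
  key <- parent_key(gm, "S001", "S002")
  expect_identical(key$classifiable, c(TRUE, FALSE, FALSE, FALSE))
  expect_identical(key$rp_allele[1], "A")
  expect_identical(key$dp_allele[1], "G")
})

test_that("sample composition proportions follow the two denominators", {
  codes <- matrix(c(rep("RP_HOM", 70), rep("DP_HOM", 20), rep("HET", 5),
                    rep("MISSING", 5)), nrow = 1)
  cm <- codes_matrix(codes)
  comp <- sample_composition(cm)
  expect_equal(comp$prop_rp_hom, 0.70)
  expect_equal(comp$prop_rp_hom_nm, 70 / 95, tolerance = 1e-6)
  expect_equal(comp$prop_dp_hom_nm, 20 / 95, tolerance = 1e-6)
  expect_equal(comp$prop_het_nm, 5 / 95, tolerance = 1e-6)
  # A-style proportions sum to 1; B-style sum to 1 over three codes
  expect_equal(comp$prop_rp_hom + comp$prop_dp_hom + comp$prop_het +
               comp$prop_missing, 1)
  expect_equal(comp$prop_rp_hom_nm + comp$prop_dp_hom_nm + comp$prop_het_nm,
               1)
})

test_that("an all-missing sample reports NA non-missing proportions", {
  codes <- rbind(rep("MISSING", 10), rep("RP_HOM", 10))
  cm <- codes_matrix(codes)
  comp <- sample_composition(cm)
  expect_equal(comp$prop_missing[1], 1)
  expect_true(is.na(comp$prop_rp_hom_nm[1]))
})

test_that("per-site allele frequencies match hand arithmetic", {
  codes <- cbind(rep("RP_HOM", 10),
                 rep("HET", 10),
                 c(rep("RP_HOM", 6), rep("DP_HOM", 3), "HET"),
                 rep("MISSING", 10))
  cm <- codes_matrix(codes)
  tr <- allele_frequency_track(cm)
  expect_equal(tr$freq_rp, c(1.0, 0.5, 13 / 20, NA))
  ok <- !is.na(tr$freq_rp)
  expect_equal(tr$freq_rp[ok] + tr$freq_dp[ok], rep(1, sum(ok)))
})

test_that("window starts follow the 10-SNP/5-SNP pattern", {
  codes <- matrix(rep("RP_HOM", 20), nrow = 1)
  cm <- codes_matrix(codes, pos = seq_len(20) * 100L)
  tr <- allele_frequency_track(cm)
  ws <- window_scan(tr, window_snps = 10L, step_snps = 5L)
  expect_equal(ws$start_pos, c(1, 6, 11, 16) * 100)
  expect_equal(ws$n_snps, c(10L, 10L, 10L, 5L))
  expect_identical(ws$partial, c(FALSE, FALSE, FALSE, TRUE))
  expect_equal(ws$mean_freq_rp, rep(1, 4))   # constancy
})

test_that("short chromosomes yield one partial window with a warning", {
  codes <- matrix(rep("HET", 4), nrow = 1)
  cm <- codes_matrix(codes)
  tr <- allele_frequency_track(cm)
  expect_warning(ws <- window_scan(tr), "fewer than")
  expect_identical(nrow(ws), 1L)
  expect_true(ws$partial)
  expect_equal(ws$mean_freq_rp, 0.5)
})

test_that("windows never span chromosomes", {
  codes <- matrix(rep("RP_HOM", 24), nrow = 1)
  cm <- codes_matrix(codes, chrom = rep(c("chr1", "chr2"), each = 12),
                     pos = rep(seq_len(12) * 100L, 2))
  tr <- allele_frequency_track(cm)
  ws <- window_scan(tr)
  expect_true(all(table(ws$chrom) == 2))
  expect_lte(max(ws$end_pos), 1200)
})

test_that("sweep flagging uses the mean + k*SD rule and merges intervals", {
  scan <- data.frame(chrom = "chr1",
                     start_pos = seq(1, 1000, by = 10),
                     end_pos = seq(10, 1009, by = 10),
                     n_snps = 10L, mean_freq_rp = 0.75,
                     mean_freq_dp = 0.25, partial = FALSE)
  set.seed(50)
  scan$mean_freq_dp <- stats::rnorm(nrow(scan), 0.25, 0.02)
  scan$mean_freq_rp <- 1 - scan$mean_freq_dp
  scan$mean_freq_dp[c(41, 42)] <- 0.9
  sw <- sweep_candidates(scan)
  expect_true(all(sw$windows$flagged[c(41, 42)]))
  expect_identical(nrow(sw$intervals), 1L)
  expect_equal(sw$intervals$n_windows, 2L)
  # flat scan: zero variance, no flags
  scan$mean_freq_dp <- 0.25
  sw2 <- sweep_candidates(scan)
  expect_false(any(sw2$windows$flagged))
  expect_identical(nrow(sw2$intervals), 0L)
})

test_that("segments are run-length intervals with optional bridging", {
  codes <- matrix(c("RP_HOM", "RP_HOM", "DP_HOM", "DP_HOM", "DP_HOM",
                    "RP_HOM"), nrow = 1)
  cm <- codes_matrix(codes, pos = c(100L, 200L, 300L, 400L, 500L, 600L))
  seg <- segments(cm)
  expect_identical(nrow(seg), 3L)
  expect_identical(seg$code, c("RP_HOM", "DP_HOM", "RP_HOM"))
  # BED convention: a 1-SNP segment at pos p is (p-1, p)
  expect_equal(seg$start[3], 599)
  expect_equal(seg$end[3], 600)

  codes2 <- matrix(c("RP_HOM", "MISSING", "RP_HOM"), nrow = 1)
  cm2 <- codes_matrix(codes2, pos = c(100L, 200L, 300L))
  expect_identical(nrow(segments(cm2, bridge_missing = TRUE)), 1L)
  expect_identical(nrow(segments(cm2, bridge_missing = FALSE)), 2L)

  cm3 <- codes_matrix(matrix(rep("MISSING", 3), nrow = 1))
  expect_identical(nrow(segments(cm3)), 0L)
})

test_that("neutral panel lands in the expected composition band", {
  set.seed(51)
  map <- random_genome_map(n_sites = 600, n_chrom = 6)
  panel <- simulate_panel(breeding_scheme(n_lines = 80), map)
  gm <- truth_genotype_matrix(panel)
  cm <- classify(gm, parent_key_from_map(map))
  tr <- allele_frequency_track(cm)
  m <- mean(tr$freq_rp, na.rm = TRUE)
  expect_gt(m, 0.70)
  expect_lt(m, 0.80)
  comp <- sample_composition(cm)
  expect_lte(mean(comp$prop_het_nm), 0.10)
})

test_that("a selected locus is flagged as a sweep candidate", {
  set.seed(52)
  map <- random_genome_map(n_sites = 600, n_chrom = 6)
  locus <- map$sites[300, ]
  sel <- data.frame(chrom = locus$chrom, pos = locus$pos,
                    mode = "require_donor_allele", rounds = 3L)
  panel <- simulate_panel(breeding_scheme(n_lines = 80, selection = sel),
                          map)
  cm <- classify(truth_genotype_matrix(panel), parent_key_from_map(map))
  ws <- window_scan(allele_frequency_track(cm))
  sw <- sweep_candidates(ws)
  hit <- sw$intervals$chrom == locus$chrom &
    sw$intervals$start_pos <= locus$pos & sw$intervals$end_pos >= locus$pos
  expect_true(any(hit))
})
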