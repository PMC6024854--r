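# Parent-based introgression profiling: classify calls against the
# recurrent/donor parent pair, summarize per-sample genome composition, run
# sliding-window parent-allele-frequency scans, flag putative selective
# sweeps, and emit per-sample introgression segments.

CODES <- c("RP_HOM", "DP_HOM", "HET", "MISSING")

#' Build a parent key from the parents' called genotypes
#'
#' A site is classifiable iff both parents are called homozygous and their
#' alleles differ; classification of line genotypes is only defined at
#' classifiable sites.
#'
#' @param gm a `genotype_matrix` containing the parent samples
#' @param rp_sample,dp_sample sample ids of the recurrent and donor parent
#' @return object of class `parent_key`: data.frame with `chrom`, `pos`,
#'   `rp_allele`, `dp_allele`, `classifiable`
#' @export
parent_key <- function(gm, rp_sample, dp_sample) {
  stopifnot(inherits(gm, "genotype_matrix"),
            rp_sample %in% gm$samples, dp_sample %in% gm$samples)
  rp <- gm$calls[rp_sample, ]
  dp <- gm$calls[dp_sample, ]
  rp_a <- split_alleles(rp); dp_a <- split_alleles(dp)
  rp_hom <- !is.na(rp) & rp_a$a1 == rp_a$a2
  dp_hom <- !is.na(dp) & dp_a$a1 == dp_a$a2
  classifiable <- rp_hom & dp_hom & rp_a$a1 != dp_a$a1
  out <- data.frame(chrom = gm$sites$chrom, pos = gm$sites$pos,
                    rp_allele = ifelse(rp_hom, rp_a$a1, NA_character_),
                    dp_allele = ifelse(dp_hom, dp_a$a1, NA_character_),
                    classifiable = classifiable)
  class(out) <- c("parent_key", "data.frame")
  out
}

#' Build a parent key directly from a genome map (simulation truth)
#'
#' @param map a [genome_map()]
#' @param donor_hap optional 0/1 donor haplotype on the map frame; sites where
#'   the donor carries the RP allele are unclassifiable
#' @return a `parent_key`
#' @export
parent_key_from_map <- function(map, donor_hap = NULL) {
  cl <- if (is.null(donor_hap)) rep(TRUE, n_sites(map)) else donor_hap == 1L
  out <- data.frame(chrom = map$sites$chrom, pos = map$sites$pos,
                    rp_allele = map$sites$rp_allele,
                    dp_allele = map$sites$dp_allele,
                    classifiable = cl)
  class(out) <- c("parent_key", "data.frame")
  out
}

#' Classify called genotypes against the parent key
#'
#' At each classifiable site: a homozygote for the RP allele -> `RP_HOM`; for
#' the DP allele -> `DP_HOM`; a heterozygote carrying exactly the RP and DP
#' alleles -> `HET`; anything else (missing call, third allele, or an
#' unclassifiable site) -> `MISSING`. Calls carrying a non-parental allele
#' are additionally counted in the `non_parental` attribute.
#'
#' @param gm a `genotype_matrix`
#' @param key a `parent_key` covering the matrix's sites
#' @return a `classified_matrix`: list with `codes` (samples x classifiable
#'   sites character matrix over RP_HOM/DP_HOM/HET/MISSING), `sites`,
#'   `samples`, and attribute-like field `non_parental` (count of calls
#'   showing an allele that is neither parent's)
#' @export
classify <- function(gm, key) {
  stopifnot(inherits(gm, "genotype_matrix"), nrow(key) == ncol(gm$calls))
  keep <- which(key$classifiable)
  calls <- gm$calls[, keep, drop = FALSE]
  rp <- key$rp_allele[keep]; dp <- key$dp_allele[keep]
  al <- split_alleles(calls)
  rp_m <- matrix(rp, nrow(calls), length(keep), byrow = TRUE)
  dp_m <- matrix(dp, nrow(calls), length(keep), byrow = TRUE)
  hom <- !is.na(calls) & al$a1 == al$a2
  het <- !is.na(calls) & al$a1 != al$a2
  codes <- matrix("MISSING", nrow(calls), length(keep),
                  dimnames = dimnames(calls))
  codes[hom & al$a1 == rp_m] <- "RP_HOM"
  codes[hom & al$a1 == dp_m] <- "DP_HOM"
  het_par <- het & ((al$a1 == rp_m & al$a2 == dp_m) |
                    (al$a1 == dp_m & al$a2 == rp_m))
  codes[het_par] <- "HET"
  nm <- !is.na(calls)
  non_parental <- sum(nm & ((al$a1 != rp_m & al$a1 != dp_m) |
                            (al$a2 != rp_m & al$a2 != dp_m)), na.rm = TRUE)
  structure(list(codes = codes, sites = gm$sites[keep, , drop = FALSE],
                 samples = gm$samples, non_parental = non_parental),
            class = "classified_matrix")
}

#' @export
print.classified_matrix <- function(x, ...) {
  cat("classified_matrix:", length(x$samples), "samples x", ncol(x$codes),
      "classifiable sites\n")
  invisible(x)
}

#' Per-sample genome composition
#'
#' Counts and proportions of the four codes per sample. A-style proportions
#' are over all classifiable sites (missing included); B-style proportions
#' are over non-missing calls only (`NA` for a sample with no non-missing
#' call). Panel-level means are attached as the `"panel_means"` attribute.
#'
#' @param cm a `classified_matrix`
#' @return data.frame, one row per sample
#' @export
sample_composition <- function(cm) {
  stopifnot(inherits(cm, "classified_matrix"))
  if (ncol(cm$codes) == 0L) stop("no classifiable sites")
  n <- ncol(cm$codes)
  cnt <- vapply(CODES, function(cd) rowSums(cm$codes == cd),
                numeric(nrow(cm$codes)))
  if (nrow(cm$codes) == 1L) cnt <- matrix(cnt, nrow = 1L,
                                          dimnames = list(NULL, CODES))
  nm <- n - cnt[, "MISSING"]
  out <- data.frame(sample = cm$samples,
                    n_rp_hom = cnt[, "RP_HOM"], n_dp_hom = cnt[, "DP_HOM"],
                    n_het = cnt[, "HET"], n_missing = cnt[, "MISSING"],
                    prop_rp_hom = cnt[, "RP_HOM"] / n,
                    prop_dp_hom = cnt[, "DP_HOM"] / n,
                    prop_het = cnt[, "HET"] / n,
                    prop_missing = cnt[, "MISSING"] / n,
                    prop_rp_hom_nm = ifelse(nm > 0, cnt[, "RP_HOM"] / nm, NA),
                    prop_dp_hom_nm = ifelse(nm > 0, cnt[, "DP_HOM"] / nm, NA),
                    prop_het_nm = ifelse(nm > 0, cnt[, "HET"] / nm, NA),
                    row.names = NULL)
  attr(out, "panel_means") <- colMeans(out[, -1], na.rm = TRUE)
  out
}

#' Per-site parent allele frequencies across samples
#'
#' `freq_rp = (2 * RP_HOM + HET) / (2 * non-missing)` per site;
#' `freq_dp = 1 - freq_rp`. Sites with no non-missing call get `NA`.
#'
#' @param cm a `classified_matrix`
#' @return data.frame: `chrom`, `pos`, `n_called`, `freq_rp`, `freq_dp`
#' @export
allele_frequency_track <- function(cm) {
  stopifnot(inherits(cm, "classified_matrix"))
  nrp <- colSums(cm$codes == "RP_HOM")
  ndp <- colSums(cm$codes == "DP_HOM")
  nhet <- colSums(cm$codes == "HET")
  ncalled <- nrp + ndp + nhet
  frp <- ifelse(ncalled > 0, (2 * nrp + nhet) / (2 * ncalled), NA_real_)
  data.frame(chrom = cm$sites$chrom, pos = cm$sites$pos,
             n_called = ncalled, freq_rp = frp, freq_dp = 1 - frp)
}

#' Sliding-window scan of parent allele frequencies
#'
#' Windows of `window_snps` SNPs advance by `step_snps` SNPs along each
#' chromosome (windows never span chromosomes). A trailing partial window is
#' kept, flagged `partial`, if it holds at least `step_snps` SNPs; a
#' chromosome with fewer than `window_snps` sites yields a single partial
#' window with a warning. Window means are unweighted means of the per-site
#' frequencies, excluding `NA` sites.
#'
#' @param track per-site frequency data.frame from [allele_frequency_track()]
#' @param window_snps window size in SNPs (default 10)
#' @param step_snps step size in SNPs (default 5)
#' @return data.frame, one row per window: `chrom`, `start_pos`, `end_pos`,
#'   `n_snps`, `mean_freq_rp`, `mean_freq_dp`, `partial`
#' @export
window_scan <- function(track, window_snps = 10L, step_snps = 5L) {
  stopifnot(step_snps >= 1L, step_snps <= window_snps)
  if (is.unsorted(order(match(track$chrom, unique(track$chrom)), track$pos)))
    track <- track[order(match(track$chrom, unique(track$chrom)), track$pos), ]
  res <- list()
  for (cc in unique(track$chrom)) {
    tr <- track[track$chrom == cc, , drop = FALSE]
    n <- nrow(tr)
    if (n < window_snps) {
      warning("chromosome ", cc, " has fewer than ", window_snps,
              " SNPs; single partial window")
      starts <- 1L
    } else {
      starts <- seq.int(1L, n, by = step_snps)
      sizes <- pmin(n - starts + 1L, window_snps)
      starts <- starts[sizes >= step_snps]
    }
    for (s in starts) {
      e <- min(s + window_snps - 1L, n)
      w <- tr[s:e, , drop = FALSE]
      res[[length(res) + 1L]] <- data.frame(
        chrom = cc, start_pos = w$pos[1], end_pos = w$pos[nrow(w)],
        n_snps = nrow(w),
        mean_freq_rp = mean(w$freq_rp, na.rm = TRUE),
        mean_freq_dp = mean(w$freq_dp, na.rm = TRUE),
        partial = nrow(w) < window_snps)
    }
  }
  out <- do.call(rbind, res)
  out$mean_freq_rp[is.nan(out$mean_freq_rp)] <- NA_real_
  out$mean_freq_dp[is.nan(out$mean_freq_dp)] <- NA_real_
  out
}

#' Flag windows with unexpectedly high donor allele frequency
#'
#' A window is flagged when its mean DP-allele frequency exceeds the
#' genome-wide window mean by more than `k_sd` window standard deviations.
#' Adjacent flagged windows on the same chromosome are merged into intervals.
#' A zero-variance scan yields no flags.
#'
#' @param scan window data.frame from [window_scan()]
#' @param k_sd flagging threshold in window SDs (default 3)
#' @return list with `windows` (the scan plus a `flagged` column) and
#'   `intervals` (data.frame of merged flagged intervals: `chrom`,
#'   `start_pos`, `end_pos`, `n_windows`, `max_freq_dp`)
#' @export
sweep_candidates <- function(scan, k_sd = 3.0) {
  if (nrow(scan) < 2L) stop("need at least 2 windows")
  m <- mean(scan$mean_freq_dp, na.rm = TRUE)
  s <- stats::sd(scan$mean_freq_dp, na.rm = TRUE)
  flagged <- if (is.na(s) || s == 0) rep(FALSE, nrow(scan))
             else !is.na(scan$mean_freq_dp) & scan$mean_freq_dp > m + k_sd * s
  scan$flagged <- flagged
  ivs <- list()
  r <- rle(paste(scan$chrom, flagged))
  idx_end <- cumsum(r$lengths)
  idx_start <- idx_end - r$lengths + 1L
  for (i in seq_along(r$lengths)) {
    if (!flagged[idx_start[i]]) next
    blk <- scan[idx_start[i]:idx_end[i], , drop = FALSE]
    ivs[[length(ivs) + 1L]] <- data.frame(
      chrom = blk$chrom[1], start_pos = min(blk$start_pos),
      end_pos = max(blk$end_pos), n_windows = nrow(blk),
      max_freq_dp = max(blk$mean_freq_dp))
  }
  intervals <- if (length(ivs)) do.call(rbind, ivs)
               else data.frame(chrom = character(0), start_pos = numeric(0),
                               end_pos = numeric(0), n_windows = integer(0),
                               max_freq_dp = numeric(0))
  list(windows = scan, intervals = intervals)
}

#' Per-sample introgression segments
#'
#' Collapses each sample's classified codes into maximal runs of identical
#' non-missing codes per chromosome. With `bridge_missing = TRUE` (default),
#' missing sites flanked by the same code are absorbed into one segment; with
#' `FALSE`, missing sites break segments. Output intervals are BED-style
#' 0-based half-open on the SNP positions spanned by the run.
#'
#' @param cm a `classified_matrix`
#' @param bridge_missing absorb interior missing sites between equal codes?
#' @return data.frame: `sample`, `chrom`, `start` (0-based), `end`, `code`,
#'   `n_snps`
#' @export
segments <- function(cm, bridge_missing = TRUE) {
  stopifnot(inherits(cm, "classified_matrix"))
  res <- list()
  for (smp in seq_along(cm$samples)) {
    for (cc in unique(cm$sites$chrom)) {
      sel <- which(cm$sites$chrom == cc)
      codes <- cm$codes[smp, sel]
      pos <- cm$sites$pos[sel]
      if (bridge_missing) {
        keep <- codes != "MISSING"
        codes <- codes[keep]; pos <- pos[keep]
      }
      if (length(codes) == 0L) next
      r <- rle(codes)
      ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
      for (i in seq_along(r$values)) {
        if (r$values[i] == "MISSING") next
        res[[length(res) + 1L]] <- data.frame(
          sample = cm$samples[smp], chrom = cc,
          start = pos[starts[i]] - 1L, end = pos[ends[i]],
          code = r$values[i], n_snps = r$lengths[i])
      }
    }
  }
  if (length(res) == 0L)
    return(data.frame(sample = character(0), chrom = character(0),
                      start = integer(0), end = integer(0),
                      code = character(0), n_snps = integer(0)))
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}
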