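# SNP filter cascade ending in the LMD50 (low-missing-data) set.
#
# A site survives iff: missing rate <= 0.80, exactly 2 alleles, >= 2 genotype
# classes, MAF >= 0.1, heterozygous-call fraction <= 0.10, and finally
# (LMD50) missing rate <= 0.50. All predicates are per-site, so the cascade
# is order-independent on the survivor set; the attrition table records
# removals at the first failing stage in this printed order.

#' Filter thresholds for the SNP cascade
#'
#' @param max_missing_initial initial missing-rate ceiling
#' @param required_allele_number exact number of alleles a site must show
#' @param min_genotype_classes minimum distinct genotype classes
#' @param min_maf minimum minor allele frequency (genotype-derived counts)
#' @param max_site_heterozygosity ceiling on the heterozygous-call fraction
#'   (inclusive)
#' @param max_missing_lmd final, stricter missing-rate ceiling defining the
#'   low-missing-data (LMD50) set
#' @return object of class `filter_thresholds`
#' @export
filter_thresholds <- function(max_missing_initial = 0.80,
                              required_allele_number = 2L,
                              min_genotype_classes = 2L,
                              min_maf = 0.10,
                              max_site_heterozygosity = 0.10,
                              max_missing_lmd = 0.50) {
  stopifnot(max_missing_initial >= 0, max_missing_initial <= 1,
            required_allele_number >= 1, min_genotype_classes >= 1,
            min_maf >= 0, min_maf <= 0.5,
            max_site_heterozygosity >= 0, max_site_heterozygosity <= 1,
            max_missing_lmd >= 0, max_missing_lmd <= 1)
  structure(list(max_missing_initial = max_missing_initial,
                 required_allele_number = as.integer(required_allele_number),
                 min_genotype_classes = as.integer(min_genotype_classes),
                 min_maf = min_maf,
                 max_site_heterozygosity = max_site_heterozygosity,
                 max_missing_lmd = max_missing_lmd),
            class = "filter_thresholds")
}

#' Per-site filter statistics
#'
#' Allele frequencies are genotype-derived: a homozygote contributes 2 copies
#' of its allele, a heterozygote 1 copy of each. `maf` is the minimum observed
#' allele frequency; `het_rate` is the heterozygous fraction of non-missing
#' calls. A site with no non-missing calls gets `missing_rate = 1` and `NA`
#' for the remaining statistics (it fails the cascade automatically).
#'
#' @param calls character vector of one site's genotypes across samples
#'   (`"X/Y"`, `NA` = missing)
#' @return list with `missing_rate`, `n_alleles`, `n_genotype_classes`,
#'   `maf`, `het_rate`
#' @export
site_stats <- function(calls) {
  n <- length(calls)
  if (n == 0L) stop("site_stats needs at least one sample")
  miss <- is.na(calls)
  obs <- calls[!miss]
  if (length(obs) == 0L)
    return(list(missing_rate = 1, n_alleles = NA_integer_,
                n_genotype_classes = NA_integer_, maf = NA_real_,
                het_rate = NA_real_))
  a1 <- substr(obs, 1L, 1L); a2 <- substr(obs, 3L, 3L)
  ac <- table(c(a1, a2))
  freq <- ac / sum(ac)
  list(missing_rate = sum(miss) / n,
       n_alleles = length(ac),
       n_genotype_classes = length(unique(obs)),
       maf = if (length(ac) < 2L) 0 else as.numeric(min(freq)),
       het_rate = mean(a1 != a2))
}

# vectorized site stats for a genotype_matrix -> data.frame, one row per site
site_stats_all <- function(gm) {
  calls <- gm$calls
  n <- nrow(calls); ns <- ncol(calls)
  al <- split_alleles(calls)
  miss <- is.na(calls)
  n_obs <- n - colSums(miss)
  count_base <- function(b)
    colSums((al$a1 == b) + (al$a2 == b), na.rm = TRUE)
  ac <- vapply(BASES, count_base, numeric(ns))
  if (ns == 1L) ac <- matrix(ac, nrow = 1L)
  tot <- rowSums(ac)
  n_alleles <- rowSums(ac > 0)
  minfreq <- apply(ifelse(ac > 0, ac, Inf), 1L, min) / tot
  minfreq[n_alleles < 2L] <- 0
  minfreq[!is.finite(minfreq) | tot == 0] <- NA_real_
  classes <- vapply(seq_len(ns), function(s) {
    o <- calls[, s]; length(unique(o[!is.na(o)]))
  }, integer(1))
  het <- colSums(al$a1 != al$a2, na.rm = TRUE)
  data.frame(missing_rate = colSums(miss) / n,
             n_alleles = ifelse(n_obs > 0, n_alleles, NA_integer_),
             n_genotype_classes = ifelse(n_obs > 0, classes, NA_integer_),
             maf = minfreq,
             het_rate = ifelse(n_obs > 0, het / n_obs, NA_real_))
}

#' Apply the SNP filter cascade
#'
#' Stages, in order: missing rate <= `max_missing_initial`; allele number ==
#' `required_allele_number`; genotype classes >= `min_genotype_classes`;
#' MAF >= `min_maf`; heterozygosity <= `max_site_heterozygosity`; and the
#' final LMD50 stage, missing rate <= `max_missing_lmd`. Sites with no
#' non-missing calls fail at the first applicable stage.
#'
#' @param gm a `genotype_matrix`
#' @param t a [filter_thresholds()]
#' @return list with `matrix` (the surviving `genotype_matrix`), `attrition`
#'   (data.frame: stage, n_in, n_removed, n_out), and `stats` (the per-site
#'   statistics of the input matrix plus the stage at which each site was
#'   removed, `NA` for survivors)
#' @export
apply_cascade <- function(gm, t = filter_thresholds()) {
  stopifnot(inherits(gm, "genotype_matrix"))
  if (ncol(gm$calls) == 0L) stop("empty genotype matrix")
  st <- site_stats_all(gm)
  ok <- function(x) !is.na(x) & x
  preds <- list(
    missing_le_initial = ok(st$missing_rate <= t$max_missing_initial),
    allele_number      = ok(st$n_alleles == t$required_allele_number),
    genotype_classes   = ok(st$n_genotype_classes >= t$min_genotype_classes),
    maf                = ok(st$maf >= t$min_maf),
    heterozygosity     = ok(st$het_rate <= t$max_site_heterozygosity),
    missing_le_lmd     = ok(st$missing_rate <= t$max_missing_lmd))
  alive <- rep(TRUE, nrow(st))
  removed_at <- rep(NA_character_, nrow(st))
  attr_tab <- data.frame(stage = names(preds), n_in = NA_integer_,
                         n_removed = NA_integer_, n_out = NA_integer_)
  for (i in seq_along(preds)) {
    attr_tab$n_in[i] <- sum(alive)
    fail <- alive & !preds[[i]]
    removed_at[fail] <- names(preds)[i]
    alive <- alive & preds[[i]]
    attr_tab$n_removed[i] <- sum(fail)
    attr_tab$n_out[i] <- sum(alive)
  }
  st$removed_at <- removed_at
  keep <- which(alive)
  out <- genotype_matrix(gm$calls[, keep, drop = FALSE],
                         gm$sites[keep, , drop = FALSE],
                         ambiguous = gm$ambiguous[, keep, drop = FALSE])
  list(matrix = out, attrition = attr_tab, stats = st)
}

#' Apply the filter cascade per sub-population
#'
#' Multi-donor panels are filtered the way they are genotyped: each
#' sub-population (its lines, its donor parent, and the shared recurrent
#' parent) gets its own cascade, and the retained matrix is the union of the
#' per-population survivor sites over all samples. This matches designs where
#' most SNPs segregate in only one donor x RP cross and would fail a pooled
#' minor-allele-frequency filter.
#'
#' @param gm a `genotype_matrix` holding all samples
#' @param populations named list: for each sub-population, the character
#'   vector of sample ids to filter on (typically lines + both parents)
#' @param t a [filter_thresholds()]
#' @return list with `matrix` (union survivor `genotype_matrix` over all
#'   samples), `per_population` (list of per-population [apply_cascade()]
#'   results), and `lmd50_counts` (named integer vector of per-population
#'   survivor counts)
#' @export
apply_cascade_by_population <- function(gm, populations,
                                        t = filter_thresholds()) {
  stopifnot(inherits(gm, "genotype_matrix"), length(populations) >= 1)
  res <- lapply(populations, function(smp) {
    stopifnot(all(smp %in% gm$samples))
    sub <- genotype_matrix(gm$calls[smp, , drop = FALSE], gm$sites,
                           ambiguous = gm$ambiguous[smp, , drop = FALSE])
    apply_cascade(sub, t)
  })
  survivors <- lapply(res, function(r)
    paste(r$matrix$sites$chrom, r$matrix$sites$pos))
  union_key <- unique(unlist(survivors))
  keep <- which(paste(gm$sites$chrom, gm$sites$pos) %in% union_key)
  out <- genotype_matrix(gm$calls[, keep, drop = FALSE],
                         gm$sites[keep, , drop = FALSE],
                         ambiguous = gm$ambiguous[, keep, drop = FALSE])
  counts <- vapply(survivors, length, integer(1))
  list(matrix = out, per_population = res, lmd50_counts = counts)
}

#' Audit that every retained site satisfies the cascade predicates
#'
#' Independent re-check of [apply_cascade()]'s output: recomputes the site
#' statistics of the filtered matrix and verifies all six predicates.
#'
#' @param gm a filtered `genotype_matrix`
#' @param t the [filter_thresholds()] used
#' @return `TRUE` invisibly; errors if any site violates a predicate
#' @export
audit_cascade <- function(gm, t = filter_thresholds()) {
  st <- site_stats_all(gm)
  bad <- which(!(st$missing_rate <= t$max_missing_lmd &
                 st$missing_rate <= t$max_missing_initial &
                 st$n_alleles == t$required_allele_number &
                 st$n_genotype_classes >= t$min_genotype_classes &
                 st$maf >= t$min_maf &
                 st$het_rate <= t$max_site_heterozygosity))
  if (length(bad))
    stop("cascade audit failed at site(s): ", paste(bad, collapse = ", "))
  invisible(TRUE)
}
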