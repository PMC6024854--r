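# Read-support genotype calling.
#
# The calling rules mirror standard tGBS practice: a site needs >= 3
# quality-passing reads to be callable in a sample; a heterozygote requires
# >= 2 reads for each of two alleles, each allele > 20% of the site's reads,
# and the two alleles together >= 90% of reads; otherwise a homozygote is
# called when the major allele has >= 3 reads.

BASES <- c("A", "C", "G", "T")

#' Genotype-calling thresholds
#'
#' @param min_site_reads minimum quality-passing reads for a site to be
#'   callable in a sample
#' @param hom_min_major_reads minimum reads supporting the major allele for a
#'   homozygous call
#' @param hom_min_base_quality PHRED floor; reads below it are masked before
#'   calling
#' @param het_min_reads_per_allele minimum reads per allele for the allele to
#'   enter the heterozygote test
#' @param het_min_allele_fraction each of the two alleles must exceed this
#'   fraction of the site's reads (strict)
#' @param het_min_two_allele_fraction the two alleles together must reach this
#'   fraction of the site's reads (inclusive)
#' @param discovery_min_reads,discovery_min_sample_fraction site discovery:
#'   keep sites with >= `discovery_min_reads` total reads in at least
#'   `discovery_min_sample_fraction` of samples
#' @return object of class `call_thresholds`
#' @export
call_thresholds <- function(min_site_reads = 3L, hom_min_major_reads = 3L,
                            hom_min_base_quality = 20L,
                            het_min_reads_per_allele = 2L,
                            het_min_allele_fraction = 0.20,
                            het_min_two_allele_fraction = 0.90,
                            discovery_min_reads = 5L,
                            discovery_min_sample_fraction = 0.50) {
  stopifnot(min_site_reads >= 1, hom_min_major_reads >= 1,
            het_min_reads_per_allele >= 1,
            het_min_allele_fraction > 0, het_min_allele_fraction <= 1,
            het_min_two_allele_fraction > 0, het_min_two_allele_fraction <= 1,
            discovery_min_reads >= 1,
            discovery_min_sample_fraction > 0,
            discovery_min_sample_fraction <= 1)
  structure(list(min_site_reads = as.integer(min_site_reads),
                 hom_min_major_reads = as.integer(hom_min_major_reads),
                 hom_min_base_quality = as.integer(hom_min_base_quality),
                 het_min_reads_per_allele = as.integer(het_min_reads_per_allele),
                 het_min_allele_fraction = het_min_allele_fraction,
                 het_min_two_allele_fraction = het_min_two_allele_fraction,
                 discovery_min_reads = as.integer(discovery_min_reads),
                 discovery_min_sample_fraction = discovery_min_sample_fraction),
            class = "call_thresholds")
}

# vectorized core: qc is an N x 4 matrix of quality-passing counts.
# Returns list(state, a1, a2, support, ambiguous) with a1/a2 base indices
# (NA when absent). Ties broken toward the lexicographically smaller base.
call_genotypes_core <- function(qc, t) {
  eps <- 1e-9
  N <- nrow(qc)
  tot <- rowSums(qc)
  cand <- qc >= t$het_min_reads_per_allele
  key <- qc
  key[!cand] <- -1L
  i1 <- max.col(key, ties.method = "first")
  v1 <- key[cbind(seq_len(N), i1)]
  key2 <- key
  key2[cbind(seq_len(N), i1)] <- -1L
  i2 <- max.col(key2, ties.method = "first")
  v2 <- key2[cbind(seq_len(N), i2)]
  het <- tot >= t$min_site_reads &
    v1 >= t$het_min_reads_per_allele & v2 >= t$het_min_reads_per_allele &
    v1 > t$het_min_allele_fraction * tot + eps &
    v2 > t$het_min_allele_fraction * tot + eps &
    (v1 + v2) >= t$het_min_two_allele_fraction * tot - eps
  j1 <- max.col(qc, ties.method = "first")
  vmax <- qc[cbind(seq_len(N), j1)]
  hom <- !het & tot >= t$min_site_reads & vmax >= t$hom_min_major_reads
  ambiguous <- hom & rowSums(qc == vmax) > 1L
  state <- rep("MISSING", N)
  state[het] <- "HET"
  state[hom] <- "HOM"
  a1 <- rep(NA_integer_, N); a2 <- rep(NA_integer_, N)
  a1[hom] <- j1[hom]
  a1[het] <- pmin(i1, i2)[het]
  a2[het] <- pmax(i1, i2)[het]
  support <- integer(N)
  support[hom] <- vmax[hom]
  support[het] <- (v1 + v2)[het]
  list(state = state, a1 = a1, a2 = a2, support = support,
       ambiguous = ambiguous)
}

#' Call one genotype from per-base read counts
#'
#' Rules, evaluated on the quality-passing counts: (1) fewer than
#' `min_site_reads` reads -> MISSING. (2) Heterozygote test first: among
#' alleles with at least `het_min_reads_per_allele` reads, take the two with
#' the most reads; if each exceeds `het_min_allele_fraction` of the reads and
#' together they reach `het_min_two_allele_fraction`, call HET. (3) Otherwise
#' HOM if the most-supported allele has `hom_min_major_reads` reads.
#' (4) Otherwise MISSING. Major-allele ties are broken toward the
#' lexicographically smaller base and flagged ambiguous.
#'
#' @param counts named integer vector of raw read counts for A, C, G, T
#' @param quality_pass_counts counts restricted to bases with quality >=
#'   `hom_min_base_quality` (defaults to `counts`)
#' @param t a [call_thresholds()]
#' @return list with `state` ("HOM", "HET" or "MISSING"), `alleles`
#'   (character vector of 0, 1 or 2 bases), `supporting_reads`, `ambiguous`
#' @export
call_genotype <- function(counts, quality_pass_counts = counts,
                          t = call_thresholds()) {
  counts <- as_base_counts(counts)
  qc <- as_base_counts(quality_pass_counts)
  if (any(counts < 0) || any(qc < 0)) stop("negative counts")
  if (any(qc > counts)) stop("quality_pass_counts exceed counts")
  r <- call_genotypes_core(matrix(qc, 1L, 4L), t)
  alleles <- switch(r$state,
                    HOM = BASES[r$a1],
                    HET = BASES[c(r$a1, r$a2)],
                    character(0))
  list(state = r$state, alleles = alleles,
       supporting_reads = r$support, ambiguous = r$ambiguous)
}

as_base_counts <- function(x) {
  if (!is.null(names(x))) {
    out <- integer(4L); names(out) <- BASES
    out[names(x)] <- as.integer(x)
    out
  } else {
    stopifnot(length(x) == 4L)
    as.integer(x)
  }
}

# quality-masked counts for a cube under thresholds t: if the cube's recorded
# base quality is below the floor, every read is masked.
quality_pass_counts <- function(cube, t) {
  if (cube$base_quality >= t$hom_min_base_quality) cube$counts
  else array(0L, dim = dim(cube$counts), dimnames = dimnames(cube$counts))
}

#' Discover candidate SNP sites in an allele-counts cube
#'
#' Keeps sites with at least `discovery_min_reads` total reads in at least
#' `discovery_min_sample_fraction` of the samples (inclusive bounds), then
#' keeps only sites that are polymorphic: the genotypes called across samples
#' must contain at least two distinct alleles.
#'
#' @param cube an `allele_counts_cube`
#' @param t a [call_thresholds()]
#' @return integer vector of retained site indices (into `cube$sites`)
#' @export
discover_sites <- function(cube, t = call_thresholds()) {
  stopifnot(inherits(cube, "allele_counts_cube"))
  nsmp <- length(cube$samples)
  if (nsmp == 0L) stop("cube has zero samples")
  depth <- rowSums(cube$counts, dims = 2)
  frac <- colMeans(depth >= t$discovery_min_reads)
  keep <- which(frac >= t$discovery_min_sample_fraction)
  if (length(keep) == 0L) return(integer(0))
  # polymorphism on called genotypes
  qc <- quality_pass_counts(cube, t)
  poly <- vapply(keep, function(s) {
    r <- call_genotypes_core(matrix(qc[, s, ], ncol = 4L), t)
    alleles <- unique(c(r$a1[!is.na(r$a1)], r$a2[!is.na(r$a2)]))
    length(alleles) >= 2L
  }, logical(1))
  keep[poly]
}

#' Call the full genotype matrix from an allele-counts cube
#'
#' Applies [discover_sites()] then [call_genotype()] (vectorized) to every
#' sample x retained site.
#'
#' @param cube an `allele_counts_cube`
#' @param t a [call_thresholds()]
#' @param discover run site discovery first? (set `FALSE` to call every site)
#' @return a `genotype_matrix`: list with `calls` (samples x sites character
#'   matrix, e.g. `"A/A"`, `"A/G"`, `NA` for missing; heterozygote alleles
#'   sorted), `ambiguous` logical matrix, `sites` metadata, `samples`
#' @export
call_matrix <- function(cube, t = call_thresholds(), discover = TRUE) {
  stopifnot(inherits(cube, "allele_counts_cube"))
  sel <- if (discover) discover_sites(cube, t) else seq_len(nrow(cube$sites))
  nsmp <- length(cube$samples)
  if (length(sel) == 0L) {
    warning("no sites retained by discovery; empty genotype matrix")
    return(genotype_matrix(
      matrix(NA_character_, nsmp, 0L, dimnames = list(cube$samples, NULL)),
      cube$sites[integer(0), , drop = FALSE]))
  }
  qc <- quality_pass_counts(cube, t)[, sel, , drop = FALSE]
  ns <- length(sel)
  qcm <- matrix(qc, nrow = nsmp * ns, ncol = 4L)
  r <- call_genotypes_core(qcm, t)
  g <- rep(NA_character_, nsmp * ns)
  hom <- r$state == "HOM"; het <- r$state == "HET"
  g[hom] <- paste0(BASES[r$a1[hom]], "/", BASES[r$a1[hom]])
  g[het] <- paste0(BASES[r$a1[het]], "/", BASES[r$a2[het]])
  calls <- matrix(g, nsmp, ns, dimnames = list(cube$samples, NULL))
  amb <- matrix(r$ambiguous, nsmp, ns, dimnames = list(cube$samples, NULL))
  genotype_matrix(calls, cube$sites[sel, , drop = FALSE], ambiguous = amb)
}

#' Construct a genotype matrix
#'
#' @param calls samples x sites character matrix of genotypes `"X/Y"` with
#'   alleles sorted, `NA` = missing
#' @param sites site metadata data.frame (`chrom`, `pos`, ...)
#' @param ambiguous optional logical matrix flagging tie-broken calls
#' @return object of class `genotype_matrix`
#' @export
genotype_matrix <- function(calls, sites, ambiguous = NULL) {
  stopifnot(is.matrix(calls), is.data.frame(sites),
            ncol(calls) == nrow(sites))
  if (is.null(rownames(calls)))
    rownames(calls) <- sprintf("S%03d", seq_len(nrow(calls)))
  rownames(sites) <- NULL
  if (is.null(ambiguous))
    ambiguous <- matrix(FALSE, nrow(calls), ncol(calls),
                        dimnames = dimnames(calls))
  structure(list(calls = calls, sites = sites, samples = rownames(calls),
                 ambiguous = ambiguous),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat("genotype_matrix:", nrow(x$calls), "samples x", ncol(x$calls),
      "sites\n")
  invisible(x)
}

# split "X/Y" calls into two allele matrices (fixed-width encoding)
split_alleles <- function(calls) {
  list(a1 = substr(calls, 1L, 1L), a2 = substr(calls, 3L, 3L))
}
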