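#' Genome map for a biallelic introgression panel
#'
#' A genome map holds the chromosome coordinate frame (physical length in bp,
#' genetic length in cM) and the ordered list of biallelic SNP sites, each with
#' the recurrent-parent (RP) and donor-parent (DP) allele. Genetic positions
#' are obtained by linear interpolation of the chromosome's cM length onto its
#' physical length.
#'
#' @param chromosomes data.frame with columns `chrom`, `length_bp`,
#'   `length_cM`.
#' @param sites data.frame with columns `chrom`, `pos` (1-based bp),
#'   `rp_allele`, `dp_allele`. Positions must be strictly increasing within a
#'   chromosome and alleles must differ at every site.
#' @return An object of class `genome_map`.
#' @export
genome_map <- function(chromosomes, sites) {
  stopifnot(is.data.frame(chromosomes), is.data.frame(sites))
  need_c <- c("chrom", "length_bp", "length_cM")
  need_s <- c("chrom", "pos", "rp_allele", "dp_allele")
  if (!all(need_c %in% names(chromosomes)))
    stop("chromosomes must have columns: ", paste(need_c, collapse = ", "))
  if (!all(need_s %in% names(sites)))
    stop("sites must have columns: ", paste(need_s, collapse = ", "))
  chromosomes$chrom <- as.character(chromosomes$chrom)
  sites$chrom <- as.character(sites$chrom)
  if (anyDuplicated(chromosomes$chrom))
    stop("duplicated chromosome ids")
  if (!all(sites$chrom %in% chromosomes$chrom))
    stop("sites reference unknown chromosomes")
  if (any(chromosomes$length_bp <= 0) || any(chromosomes$length_cM < 0))
    stop("chromosome lengths must be positive (bp) and non-negative (cM)")
  bases <- c("A", "C", "G", "T")
  if (!all(sites$rp_allele %in% bases) || !all(sites$dp_allele %in% bases))
    stop("alleles must be A/C/G/T")
  if (any(sites$rp_allele == sites$dp_allele))
    stop("rp_allele and dp_allele must differ at every site")
  # enforce (chrom-order, pos) sort and strict increase within chromosome
  ord <- order(match(sites$chrom, chromosomes$chrom), sites$pos)
  sites <- sites[ord, , drop = FALSE]
  for (cc in unique(sites$chrom)) {
    p <- sites$pos[sites$chrom == cc]
    if (any(diff(p) <= 0))
      stop("positions must be strictly increasing within chromosome ", cc)
    if (any(p < 1) || any(p > chromosomes$length_bp[chromosomes$chrom == cc]))
      stop("site position outside chromosome ", cc)
  }
  rownames(sites) <- NULL
  # genetic position of each site (cM), linear interpolation
  idx <- match(sites$chrom, chromosomes$chrom)
  sites$cM <- sites$pos / chromosomes$length_bp[idx] * chromosomes$length_cM[idx]
  site_index <- split(seq_len(nrow(sites)),
                      factor(sites$chrom, levels = chromosomes$chrom))
  structure(list(chromosomes = chromosomes, sites = sites,
                 site_index = site_index),
            class = "genome_map")
}

#' @export
print.genome_map <- function(x, ...) {
  cat("genome_map:", nrow(x$chromosomes), "chromosomes,",
      nrow(x$sites), "sites\n")
  invisible(x)
}

#' Number of sites in a genome map
#' @param map a `genome_map`
#' @return integer
#' @export
n_sites <- function(map) nrow(map$sites)

#' Draw a random genome map
#'
#' Convenience generator for simulation studies: `n_chrom` chromosomes of
#' equal physical and genetic length, with `n_sites` SNP sites placed uniformly
#' at random (distinct positions) and RP/DP alleles drawn at random.
#' Uses the current RNG state; call [set.seed()] for reproducibility.
#'
#' @param n_sites total number of SNP sites across the genome
#' @param n_chrom number of chromosomes (default 12, a rice-like karyotype)
#' @param length_bp physical length per chromosome in bp
#' @param length_cM genetic length per chromosome in cM
#' @return a `genome_map`
#' @export
random_genome_map <- function(n_sites = 2000, n_chrom = 12,
                              length_bp = 30e6, length_cM = 150) {
  stopifnot(n_sites >= n_chrom)
  chroms <- data.frame(chrom = sprintf("chr%02d", seq_len(n_chrom)),
                       length_bp = length_bp, length_cM = length_cM)
  per <- rep(n_sites %/% n_chrom, n_chrom)
  extra <- n_sites %% n_chrom
  if (extra > 0) per[seq_len(extra)] <- per[seq_len(extra)] + 1L
  bases <- c("A", "C", "G", "T")
  site_list <- lapply(seq_len(n_chrom), function(i) {
    pos <- sort(sample.int(length_bp, per[i]))
    rp <- sample(bases, per[i], replace = TRUE)
    shift <- sample.int(3, per[i], replace = TRUE)
    dp <- bases[((match(rp, bases) - 1L + shift) %% 4L) + 1L]
    data.frame(chrom = chroms$chrom[i], pos = pos, rp_allele = rp,
               dp_allele = dp)
  })
  genome_map(chroms, do.call(rbind, site_list))
}

#' Breeding scheme for an introgression-line panel
#'
#' Describes the pedigree used to derive each line: an F1 between the
#' recurrent and donor parent, `n_backcrosses` crosses back to the recurrent
#' parent, then `n_selfing_generations` rounds of single-seed-descent selfing.
#' The default (1 backcross, 4 selfings) yields BC1F5 lines.
#'
#' Optional `selection` emulates stress screening: a data.frame of loci with
#' columns `chrom`, `pos`, `mode` (`"require_donor_allele"` or
#' `"require_donor_homozygote"`) and `rounds`. Selection on a locus is applied
#' by rejection sampling at the last `rounds` generation transitions of the
#' pedigree: offspring failing the predicate are redrawn (up to `redraw_cap`
#' draws); a line whose parent cannot produce a passing offspring is restarted
#' from the F1 (up to `line_restart_cap` restarts, then an error).
#'
#' @param n_lines number of independent lines to derive
#' @param n_backcrosses backcrosses to the recurrent parent (default 1)
#' @param n_selfing_generations selfing generations after backcrossing
#'   (default 4)
#' @param selection optional selection data.frame (see Details)
#' @param redraw_cap maximum offspring redraws per transition under selection
#' @param line_restart_cap maximum line restarts before erroring
#' @return an object of class `breeding_scheme`
#' @export
breeding_scheme <- function(n_lines, n_backcrosses = 1L,
                            n_selfing_generations = 4L, selection = NULL,
                            redraw_cap = 1000L, line_restart_cap = 100L) {
  stopifnot(n_lines >= 1, n_backcrosses >= 0, n_selfing_generations >= 0,
            redraw_cap >= 1, line_restart_cap >= 1)
  if (!is.null(selection)) {
    stopifnot(is.data.frame(selection),
              all(c("chrom", "pos", "mode", "rounds") %in% names(selection)))
    if (!all(selection$mode %in% c("require_donor_allele",
                                   "require_donor_homozygote")))
      stop("unknown selection mode")
    if (any(selection$rounds < 1)) stop("selection rounds must be >= 1")
  }
  structure(list(n_lines = as.integer(n_lines),
                 n_backcrosses = as.integer(n_backcrosses),
                 n_selfing_generations = as.integer(n_selfing_generations),
                 selection = selection,
                 redraw_cap = as.integer(redraw_cap),
                 line_restart_cap = as.integer(line_restart_cap)),
            class = "breeding_scheme")
}

#' Read-count model for tGBS-like sequencing
#'
#' Per sample and site, total depth is negative binomial with mean
#' `mean_depth` and dispersion (size) `depth_dispersion`; with probability
#' `site_dropout_rate` the site yields no reads at all for that sample
#' (emulating restriction-site presence/absence). Each read's base is drawn
#' from the true genotype (1/2-1/2 for heterozygotes) and flipped to a
#' uniformly chosen other base with probability `base_error_rate`. All
#' simulated base calls carry PHRED quality `quality_of_good_base`.
#'
#' @param mean_depth mean reads per sample per site
#' @param depth_dispersion negative-binomial size parameter (smaller = more
#'   over-dispersed)
#' @param base_error_rate per-read base miscall probability, in `[0, 1)`
#' @param site_dropout_rate probability a sample x site cell has zero depth
#' @param quality_of_good_base PHRED quality attached to simulated bases
#' @return an object of class `read_model`
#' @export
read_model <- function(mean_depth = 10, depth_dispersion = 2,
                       base_error_rate = 0.005, site_dropout_rate = 0.1,
                       quality_of_good_base = 30L) {
  stopifnot(mean_depth >= 0, depth_dispersion > 0,
            base_error_rate >= 0, base_error_rate < 1,
            site_dropout_rate >= 0, site_dropout_rate < 1,
            quality_of_good_base >= 0)
  structure(list(mean_depth = mean_depth,
                 depth_dispersion = depth_dispersion,
                 base_error_rate = base_error_rate,
                 site_dropout_rate = site_dropout_rate,
                 quality_of_good_base = as.integer(quality_of_good_base)),
            class = "read_model")
}
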