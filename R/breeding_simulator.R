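# Breeding-design simulator: meiosis without crossover interference
# (Haldane model), single-seed-descent pedigrees, and tGBS-like read counts.
#
# Individuals are represented as a pair of haplotype vectors over the map's
# sites, coded 0 = recurrent-parent allele, 1 = donor-parent allele.

#' Simulate one gamete from a diploid parent
#'
#' Meiosis without crossover interference: per chromosome the crossover count
#' is Poisson with mean `genetic_length_cM / 100` and crossover positions are
#' uniform on the genetic map, so recombination between two sites follows the
#' Haldane map function.
#'
#' @param parent list with elements `hap1`, `hap2`: integer vectors (one entry
#'   per map site, 0/1 coding) of the parent's two haplotypes.
#' @param map a [genome_map()]
#' @return integer vector: the gamete's allele (0/1) at every map site.
#' @export
simulate_gamete <- function(parent, map) {
  ns <- n_sites(map)
  if (ns == 0L) stop("empty genome map")
  stopifnot(length(parent$hap1) == ns, length(parent$hap2) == ns)
  out <- integer(ns)
  chroms <- map$chromosomes
  site_index <- map$site_index
  if (is.null(site_index))
    site_index <- split(seq_len(ns),
                        factor(map$sites$chrom, levels = chroms$chrom))
  site_cM <- map$sites$cM
  for (i in seq_len(nrow(chroms))) {
    sel <- site_index[[i]]
    if (length(sel) == 0L) next
    len_cM <- chroms$length_cM[i]
    k <- stats::rpois(1L, len_cM / 100)
    start <- sample.int(2L, 1L)
    if (k == 0L || len_cM == 0) {
      hap_idx <- rep.int(start, length(sel))
    } else {
      xo <- sort(stats::runif(k, 0, len_cM))
      n_below <- findInterval(site_cM[sel], xo)
      hap_idx <- ((start - 1L + n_below) %% 2L) + 1L
    }
    h1 <- parent$hap1[sel]; h2 <- parent$hap2[sel]
    out[sel] <- ifelse(hap_idx == 1L, h1, h2)
  }
  out
}

# diploid founders on the 0/1 coding
founder_rp <- function(map) {
  z <- integer(n_sites(map)); list(hap1 = z, hap2 = z)
}
founder_dp <- function(map, donor_hap = NULL) {
  h <- if (is.null(donor_hap)) rep(1L, n_sites(map)) else as.integer(donor_hap)
  stopifnot(length(h) == n_sites(map), all(h %in% c(0L, 1L)))
  list(hap1 = h, hap2 = h)
}

# selection predicate on an individual at pre-resolved site indices
selection_ok <- function(ind, sel_idx, sel_mode) {
  dose <- ind$hap1[sel_idx] + ind$hap2[sel_idx]
  all(ifelse(sel_mode == "require_donor_allele", dose >= 1L, dose == 2L))
}

# one generation transition with optional rejection-sampling selection
next_generation <- function(parent, map, cross_to, sel_idx, sel_mode,
                            redraw_cap) {
  if (length(sel_idx)) {
    # short-circuit transitions whose predicate no offspring can satisfy
    dose <- parent$hap1[sel_idx] + parent$hap2[sel_idx]
    feasible <- if (is.null(cross_to)) dose >= 1L
                else ifelse(sel_mode == "require_donor_allele",
                            dose >= 1L, FALSE)
    if (!all(feasible)) return(NULL)
  }
  for (try in seq_len(redraw_cap)) {
    child <- if (is.null(cross_to)) {
      list(hap1 = simulate_gamete(parent, map),
           hap2 = simulate_gamete(parent, map))
    } else {
      list(hap1 = simulate_gamete(cross_to, map),
           hap2 = simulate_gamete(parent, map))
    }
    if (length(sel_idx) == 0L || selection_ok(child, sel_idx, sel_mode))
      return(child)
  }
  NULL
}

#' Simulate an introgression-line panel under a breeding scheme
#'
#' Each line descends independently from its own F1 (recurrent x donor
#' parent): `n_backcrosses` crosses to the recurrent parent, then
#' `n_selfing_generations` single-seed-descent selfings. With the defaults
#' this produces BC1F5 lines, whose neutral expectations are a
#' recurrent-parent allele frequency of 0.75 and per-site heterozygosity of
#' 0.5 * (1/2)^4 = 0.03125.
#'
#' Selection loci (see [breeding_scheme()]) are enforced by rejection sampling
#' at the last `rounds` generation transitions of the pedigree.
#'
#' @param scheme a [breeding_scheme()]
#' @param map a [genome_map()]
#' @param donor_hap optional 0/1 vector giving the donor parent's haplotype on
#'   the map's RP/DP allele frame (default: donor carries the DP allele
#'   everywhere)
#' @param line_prefix prefix for line ids
#' @param donor_label provenance label stored with the panel
#' @param seed optional integer; if given, `set.seed(seed)` is called first
#' @return an object of class `truth_panel`: list with `geno` (lines x sites
#'   DP-allele dosage 0/1/2), `hap1`/`hap2` haplotype matrices, `map`,
#'   `line_ids`, `donor`, `generation`.
#' @export
simulate_panel <- function(scheme, map, donor_hap = NULL,
                           line_prefix = "IL", donor_label = "DP",
                           seed = NULL) {
  stopifnot(inherits(scheme, "breeding_scheme"), inherits(map, "genome_map"))
  if (!is.null(seed)) set.seed(seed)
  ns <- n_sites(map)
  rp <- founder_rp(map)
  dp <- founder_dp(map, donor_hap)
  n_trans <- scheme$n_backcrosses + scheme$n_selfing_generations

  sel_idx <- integer(0); sel_mode <- character(0); sel_rounds <- integer(0)
  if (!is.null(scheme$selection)) {
    key_map <- paste(map$sites$chrom, map$sites$pos)
    sel_idx <- match(paste(scheme$selection$chrom, scheme$selection$pos),
                     key_map)
    if (anyNA(sel_idx)) stop("selection locus not found in genome map")
    sel_mode <- scheme$selection$mode
    sel_rounds <- pmin(as.integer(scheme$selection$rounds), n_trans)
  }

  hap1 <- matrix(0L, scheme$n_lines, ns)
  hap2 <- matrix(0L, scheme$n_lines, ns)
  for (l in seq_len(scheme$n_lines)) {
    ok <- FALSE
    for (restart in seq_len(scheme$line_restart_cap)) {
      ind <- list(hap1 = rp$hap1, hap2 = dp$hap1)  # F1
      failed <- FALSE
      for (g in seq_len(n_trans)) {
        rounds_left <- n_trans - g + 1L  # transitions remaining incl. this
        active <- which(sel_rounds >= rounds_left)
        cross_to <- if (g <= scheme$n_backcrosses) rp else NULL
        child <- next_generation(ind, map, cross_to,
                                 sel_idx[active], sel_mode[active],
                                 scheme$redraw_cap)
        if (is.null(child)) { failed <- TRUE; break }
        ind <- child
      }
      if (!failed) { ok <- TRUE; break }
    }
    if (!ok)
      stop("selection predicate unsatisfiable: line restart cap exhausted ",
           "(is require_donor_homozygote feasible in that generation?)")
    hap1[l, ] <- ind$hap1
    hap2[l, ] <- ind$hap2
  }
  line_ids <- sprintf("%s%03d", line_prefix, seq_len(scheme$n_lines))
  rownames(hap1) <- rownames(hap2) <- line_ids
  structure(list(geno = hap1 + hap2, hap1 = hap1, hap2 = hap2, map = map,
                 line_ids = line_ids,
                 donor = rep(donor_label, scheme$n_lines),
                 generation = sprintf("BC%dF%d", scheme$n_backcrosses,
                                      scheme$n_selfing_generations + 1L)),
            class = "truth_panel")
}

#' @export
print.truth_panel <- function(x, ...) {
  cat("truth_panel:", length(x$line_ids), "lines x", ncol(x$geno),
      "sites (", x$generation[1], ")\n")
  invisible(x)
}

# n_gen rounds of single-seed-descent selfing
self_descend <- function(ind, map, n_gen) {
  for (g in seq_len(n_gen))
    ind <- list(hap1 = simulate_gamete(ind, map),
                hap2 = simulate_gamete(ind, map))
  ind
}

#' Simulate the full multi-donor crossing design
#'
#' One shared recurrent parent crossed to each of `n_donors` donors with
#' mutually distinct haplotypes, producing `n_lines_per_donor` lines per
#' donor. Each donor carries the map's DP allele at an independent random
#' subset of sites (density `donor_density`) and the RP allele elsewhere, so
#' donors are distinct inbred lines on a shared biallelic frame. The parents
#' themselves are appended to the returned panel (labels `RP`, `DP01`, ...).
#'
#' Unlike [simulate_panel()], lines within a sub-population share backcross
#' ancestry: each sub-population's lines descend by single-seed-descent
#' selfing from `n_founders` shared BC1 plants (default 1), reflecting the
#' bulked backcross seed from which real sub-populations are screened. This
#' shared ancestry is what gives each sub-population its joint introgression
#' signature (and hence its own cluster in a diversity tree); with fully
#' independent pedigrees the between-donor signal drowns in segregation
#' variance.
#'
#' @param map a [genome_map()]
#' @param n_donors number of donor parents
#' @param n_lines_per_donor introgression lines per donor
#' @param site_assignment `"private"` (default): the map's sites are
#'   partitioned round-robin among donors and each donor carries the DP
#'   allele exactly at its own share — emulating GBS panels where most SNPs
#'   are polymorphisms private to one donor x RP cross. `"random"`: each
#'   donor carries the DP allele at an independent random subset of density
#'   `donor_density`.
#' @param donor_density per-site DP probability for `site_assignment =
#'   "random"`
#' @param n_backcrosses,n_selfing_generations pedigree depth per line
#' @param n_founders shared backcross founders per sub-population
#' @param include_parents append RP and donor parents as panel rows?
#' @param seed optional integer seed
#' @return a `truth_panel` whose `donor` field labels each row's lineage
#'   (`RP` for the recurrent parent, `DP<k>` for donor k and its lines);
#'   the donor haplotypes are kept in the `donor_haps` field
#' @export
simulate_design_panel <- function(map, n_donors = 11, n_lines_per_donor = 8,
                                  site_assignment = c("private", "random"),
                                  donor_density = 0.5, n_backcrosses = 1L,
                                  n_selfing_generations = 4L, n_founders = 1L,
                                  include_parents = TRUE, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  site_assignment <- match.arg(site_assignment)
  stopifnot(n_founders >= 1)
  ns <- n_sites(map)
  rp <- founder_rp(map)
  donor_haps <- if (site_assignment == "private") {
    owner <- rep_len(seq_len(n_donors), ns)
    lapply(seq_len(n_donors), function(d) as.integer(owner == d))
  } else {
    lapply(seq_len(n_donors), function(d)
      stats::rbinom(ns, 1L, donor_density))
  }
  geno <- hap1 <- hap2 <- NULL
  donor <- character(0); ids <- character(0)
  for (d in seq_len(n_donors)) {
    lab <- sprintf("DP%02d", d)
    f1 <- list(hap1 = rp$hap1, hap2 = as.integer(donor_haps[[d]]))
    founders <- lapply(seq_len(n_founders), function(f) {
      ind <- f1
      for (b in seq_len(n_backcrosses))
        ind <- list(hap1 = simulate_gamete(rp, map),
                    hap2 = simulate_gamete(ind, map))
      ind
    })
    for (l in seq_len(n_lines_per_donor)) {
      fo <- founders[[((l - 1L) %% n_founders) + 1L]]
      ind <- self_descend(fo, map, n_selfing_generations)
      hap1 <- rbind(hap1, ind$hap1); hap2 <- rbind(hap2, ind$hap2)
      donor <- c(donor, lab)
      ids <- c(ids, sprintf("%s_IL%03d", lab, l))
    }
  }
  geno <- hap1 + hap2
  if (include_parents) {
    par_hap <- rbind(RP = rep(0L, ns),
                     do.call(rbind, lapply(donor_haps, as.integer)))
    rownames(par_hap) <- c("RP", sprintf("DP%02d", seq_len(n_donors)))
    geno <- rbind(geno, par_hap * 2L)
    hap1 <- rbind(hap1, par_hap)
    hap2 <- rbind(hap2, par_hap)
    donor <- c(donor, rownames(par_hap))
    ids <- c(ids, rownames(par_hap))
  }
  rownames(geno) <- rownames(hap1) <- rownames(hap2) <- ids
  structure(list(geno = geno, hap1 = hap1, hap2 = hap2, map = map,
                 line_ids = ids, donor = donor,
                 donor_haps = donor_haps,
                 generation = sprintf("BC%dF%d", n_backcrosses,
                                      n_selfing_generations + 1L)),
            class = "truth_panel")
}

#' Simulate tGBS-like allele read counts from a truth panel
#'
#' See [read_model()] for the depth and error model. Counts are returned as an
#' `allele_counts_cube`: a samples x sites x 4 (A,C,G,T) integer array plus
#' site metadata; all simulated bases carry the model's
#' `quality_of_good_base`, recorded in the cube's `base_quality` field.
#'
#' @param panel a `truth_panel`
#' @param model a [read_model()]
#' @param seed optional integer seed
#' @return an object of class `allele_counts_cube`
#' @export
simulate_read_counts <- function(panel, model, seed = NULL) {
  stopifnot(inherits(panel, "truth_panel"), inherits(model, "read_model"))
  if (!is.null(seed)) set.seed(seed)
  nl <- nrow(panel$geno); ns <- ncol(panel$geno)
  if (nl == 0L || ns == 0L) stop("empty panel")
  bases <- c("A", "C", "G", "T")
  N <- nl * ns
  depth <- stats::rnbinom(N, size = model$depth_dispersion,
                          mu = model$mean_depth)
  if (model$site_dropout_rate > 0)
    depth[stats::runif(N) < model$site_dropout_rate] <- 0L
  g <- as.vector(panel$geno)                       # DP dosage 0/1/2
  n_dp <- stats::rbinom(N, depth, g / 2)
  n_rp <- depth - n_dp
  counts <- array(0L, dim = c(nl, ns, 4L),
                  dimnames = list(rownames(panel$geno), NULL, bases))
  rp_idx <- match(panel$map$sites$rp_allele, bases)  # per site
  dp_idx <- match(panel$map$sites$dp_allele, bases)
  rp_cell <- rep(rp_idx, each = nl)                  # per cell (sample-major)
  dp_cell <- rep(dp_idx, each = nl)
  e <- model$base_error_rate
  err_rp <- if (e > 0) stats::rbinom(N, n_rp, e) else integer(N)
  err_dp <- if (e > 0) stats::rbinom(N, n_dp, e) else integer(N)
  cell <- seq_len(N)
  counts[cbind(arrayInd(cell, c(nl, ns)), rp_cell)] <- n_rp - err_rp
  counts[cbind(arrayInd(cell, c(nl, ns)), dp_cell)] <-
    counts[cbind(arrayInd(cell, c(nl, ns)), dp_cell)] + (n_dp - err_dp)
  if (e > 0 && (sum(err_rp) + sum(err_dp)) > 0) {
    # expand error reads; each flips to one of the 3 other bases uniformly
    origin <- c(rep(rp_cell, err_rp), rep(dp_cell, err_dp))
    where <- c(rep(cell, err_rp), rep(cell, err_dp))
    off <- sample.int(3L, length(origin), replace = TRUE)
    target <- ((origin - 1L + off) %% 4L) + 1L
    tab <- table(factor(where, levels = NULL), target)
    w <- as.integer(rownames(tab))
    for (b in colnames(tab)) {
      bi <- as.integer(b)
      add <- tab[, b]
      nz <- which(add > 0)
      if (length(nz)) {
        ai <- arrayInd(w[nz], c(nl, ns))
        counts[cbind(ai, bi)] <- counts[cbind(ai, bi)] + as.integer(add[nz])
      }
    }
  }
  storage.mode(counts) <- "integer"
  allele_counts_cube(counts, sites = panel$map$sites[, c("chrom", "pos",
                                                         "rp_allele",
                                                         "dp_allele")],
                     base_quality = model$quality_of_good_base)
}

#' Convert a truth panel to an error-free genotype matrix
#'
#' Maps each line's true DP-allele dosage onto the map's RP/DP alleles
#' (0 -> RP homozygote, 1 -> heterozygote, 2 -> DP homozygote), with no
#' missingness — the idealized genotyping limit, useful for validating the
#' caller and for truth-level analyses.
#'
#' @param panel a `truth_panel`
#' @return a `genotype_matrix`
#' @export
truth_genotype_matrix <- function(panel) {
  stopifnot(inherits(panel, "truth_panel"))
  rp <- panel$map$sites$rp_allele
  dp <- panel$map$sites$dp_allele
  lo <- pmin(rp, dp); hi <- pmax(rp, dp)
  n <- nrow(panel$geno); ns <- ncol(panel$geno)
  rp_g <- matrix(paste0(rp, "/", rp), n, ns, byrow = TRUE)
  dp_g <- matrix(paste0(dp, "/", dp), n, ns, byrow = TRUE)
  het_g <- matrix(paste0(lo, "/", hi), n, ns, byrow = TRUE)
  calls <- rp_g
  calls[panel$geno == 1L] <- het_g[panel$geno == 1L]
  calls[panel$geno == 2L] <- dp_g[panel$geno == 2L]
  rownames(calls) <- rownames(panel$geno)
  genotype_matrix(calls, panel$map$sites[, c("chrom", "pos", "rp_allele",
                                             "dp_allele")])
}

#' Construct an allele-counts cube
#'
#' @param counts integer array, samples x sites x 4 with base dimnames
#'   A, C, G, T on the third margin
#' @param sites data.frame of site metadata with at least `chrom`, `pos`
#' @param base_quality PHRED quality carried by the counted bases (a single
#'   summary value; bases below the caller's quality floor are masked at call
#'   time)
#' @return object of class `allele_counts_cube`
#' @export
allele_counts_cube <- function(counts, sites, base_quality = 30L) {
  stopifnot(length(dim(counts)) == 3L, dim(counts)[3] == 4L,
            is.data.frame(sites), nrow(sites) == dim(counts)[2],
            all(c("chrom", "pos") %in% names(sites)))
  if (is.null(dimnames(counts)[[3]]))
    dimnames(counts)[[3]] <- c("A", "C", "G", "T")
  if (any(counts < 0)) stop("negative read counts")
  samples <- dimnames(counts)[[1]]
  if (is.null(samples))
    samples <- sprintf("S%03d", seq_len(dim(counts)[1]))
  dimnames(counts)[[1]] <- samples
  rownames(sites) <- NULL
  structure(list(counts = counts, sites = sites, samples = samples,
                 base_quality = as.integer(base_quality)),
            class = "allele_counts_cube")
}

#' @export
print.allele_counts_cube <- function(x, ...) {
  cat("allele_counts_cube:", length(x$samples), "samples x",
      nrow(x$sites), "sites (base quality", x$base_quality, ")\n")
  invisible(x)
}
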