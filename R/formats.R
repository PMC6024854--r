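# Standard-format I/O: VCF (allele-depth cubes and genotype matrices), TSV
# matrices and tracks, BED segments, Newick trees (via ape), and the
# key-value run configuration.

#' Write an allele-counts cube as VCF 4.2
#'
#' One record per site, REF = RP allele; ALT lists the DP allele first plus
#' any other base observed in the cube, so the per-sample `AD` field (REF
#' then ALT depths) preserves the full 4-base counts. Genotypes are left
#' uncalled (`./.`); `DP` is the total depth. The cube's base quality is
#' recorded in a `##tgbs_base_quality` header line so that read/write
#' round-trips are lossless.
#'
#' @param cube an `allele_counts_cube`
#' @param path output file (plain text `.vcf`)
#' @param map optional [genome_map()] supplying `##contig` header lengths
#' @return `path`, invisibly
#' @export
write_counts_vcf <- function(cube, path, map = NULL) {
  stopifnot(inherits(cube, "allele_counts_cube"))
  nsmp <- length(cube$samples); ns <- nrow(cube$sites)
  hdr <- c("##fileformat=VCFv4.2",
           "##source=introgressr",
           sprintf("##tgbs_base_quality=%d", cube$base_quality),
           "##INFO=<ID=.,Number=0,Type=Flag,Description=\"None\">",
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
           paste0("##FORMAT=<ID=AD,Number=R,Type=Integer,Description=",
                  "\"Allelic depths (REF first)\">"),
           "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Depth\">")
  if (!is.null(map))
    hdr <- c(hdr, sprintf("##contig=<ID=%s,length=%d>",
                          map$chromosomes$chrom, map$chromosomes$length_bp))
  else
    hdr <- c(hdr, sprintf("##contig=<ID=%s>", unique(cube$sites$chrom)))
  lines <- character(ns)
  for (s in seq_len(ns)) {
    ref <- cube$sites$rp_allele[s]
    cnt <- matrix(cube$counts[, s, ], nrow = nsmp, ncol = 4L)
    colnames(cnt) <- BASES
    others <- setdiff(BASES, ref)
    seen <- others[colSums(cnt[, others, drop = FALSE]) > 0]
    dp_first <- cube$sites$dp_allele[s]
    alts <- unique(c(dp_first, seen))
    ad_cols <- c(ref, alts)
    ad <- apply(cnt[, ad_cols, drop = FALSE], 1L, paste, collapse = ",")
    dp <- rowSums(cnt)
    smp <- sprintf("./.:%s:%d", ad, dp)
    lines[s] <- paste(c(cube$sites$chrom[s], cube$sites$pos[s], ".",
                        ref, paste(alts, collapse = ","), ".", "PASS", ".",
                        "GT:AD:DP", smp), collapse = "\t")
  }
  col_hdr <- paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                     "INFO", "FORMAT", cube$samples), collapse = "\t")
  writeLines(c(hdr, col_hdr, lines), path)
  invisible(path)
}

#' Read an allele-counts cube from a VCF with AD fields
#'
#' Reconstructs per-base counts from each record's REF/ALT alleles and the
#' per-sample `AD` field (bases not listed get zero). Errors if the `AD`
#' FORMAT field is absent or if positions are not sorted within a
#' chromosome.
#'
#' @param path VCF file
#' @return an `allele_counts_cube`
#' @export
read_counts_vcf <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- v@fix
  chrom <- fix[, "CHROM"]; pos <- as.integer(fix[, "POS"])
  for (cc in unique(chrom)) {
    p <- pos[chrom == cc]
    if (is.unsorted(p, strictly = TRUE))
      stop("VCF positions not strictly sorted on ", cc, " near position ",
           p[which(diff(p) <= 0)[1] + 1L])
  }
  if (!any(grepl("AD", v@gt[, "FORMAT"])))
    stop("VCF lacks the per-sample AD (allelic depth) FORMAT field")
  ad <- vcfR::extract.gt(v, element = "AD")
  samples <- colnames(ad)
  ns <- nrow(fix); nsmp <- length(samples)
  counts <- array(0L, dim = c(nsmp, ns, 4L),
                  dimnames = list(samples, NULL, BASES))
  for (s in seq_len(ns)) {
    alleles <- c(fix[s, "REF"], strsplit(fix[s, "ALT"], ",")[[1]])
    idx <- match(alleles, BASES)
    parts <- strsplit(ad[s, ], ",")
    m <- do.call(rbind, lapply(parts, function(x) as.integer(x)))
    for (a in seq_along(idx))
      if (!is.na(idx[a])) counts[, s, idx[a]] <- m[, a]
  }
  bq <- 30L
  meta_line <- grep("^##tgbs_base_quality=", v@meta, value = TRUE)
  if (length(meta_line))
    bq <- as.integer(sub("^##tgbs_base_quality=", "", meta_line[1]))
  alt1 <- vapply(strsplit(fix[, "ALT"], ","), `[`, character(1), 1L)
  sites <- data.frame(chrom = chrom, pos = pos,
                      rp_allele = fix[, "REF"], dp_allele = alt1)
  allele_counts_cube(counts, sites, base_quality = bq)
}

#' Write a genotype matrix as VCF 4.2 (GT field)
#'
#' REF/ALT are taken from the site metadata when RP/DP alleles are present,
#' otherwise from the observed alleles. Calls with an allele outside REF/ALT
#' are written as missing.
#'
#' @param gm a `genotype_matrix`
#' @param path output file
#' @return `path`, invisibly
#' @export
write_genotype_vcf <- function(gm, path) {
  ns <- ncol(gm$calls)
  al <- split_alleles(gm$calls)
  lines <- character(ns)
  for (s in seq_len(ns)) {
    obs <- unique(stats::na.omit(c(al$a1[, s], al$a2[, s])))
    if (!is.null(gm$sites$rp_allele)) {
      ref <- gm$sites$rp_allele[s]
      alts <- unique(c(gm$sites$dp_allele[s], setdiff(obs, ref)))
    } else {
      ref <- obs[1]; alts <- setdiff(obs, ref)
      if (length(alts) == 0L) alts <- "."
    }
    allele_set <- c(ref, alts)
    g1 <- match(al$a1[, s], allele_set) - 1L
    g2 <- match(al$a2[, s], allele_set) - 1L
    gt <- ifelse(is.na(g1) | is.na(g2), "./.", paste0(g1, "/", g2))
    lines[s] <- paste(c(gm$sites$chrom[s], gm$sites$pos[s], ".", ref,
                        paste(alts, collapse = ","), ".", "PASS", ".", "GT",
                        gt), collapse = "\t")
  }
  hdr <- c("##fileformat=VCFv4.2", "##source=introgressr",
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
           sprintf("##contig=<ID=%s>", unique(gm$sites$chrom)))
  col_hdr <- paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                     "INFO", "FORMAT", gm$samples), collapse = "\t")
  writeLines(c(hdr, col_hdr, lines), path)
  invisible(path)
}

#' Write / read a genotype matrix as TSV
#'
#' Wide layout: `chrom`, `pos` (plus any further site columns), then one
#' column per sample holding `"X/Y"` calls (`NA` = missing).
#'
#' @param gm a `genotype_matrix`
#' @param path file path
#' @return `path` invisibly (write); a `genotype_matrix` (read)
#' @export
write_genotype_tsv <- function(gm, path) {
  df <- cbind(gm$sites, as.data.frame(t(gm$calls)))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_genotype_tsv
#' @param site_cols columns of the TSV holding site metadata
#' @export
read_genotype_tsv <- function(path, site_cols = NULL) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          colClasses = "character")
  if (is.null(site_cols))
    site_cols <- intersect(c("chrom", "pos", "rp_allele", "dp_allele", "cM"),
                           names(df))
  sites <- df[, site_cols, drop = FALSE]
  sites$pos <- as.integer(sites$pos)
  if ("cM" %in% names(sites)) sites$cM <- as.numeric(sites$cM)
  calls <- t(as.matrix(df[, setdiff(names(df), site_cols), drop = FALSE]))
  calls[calls == "NA" | calls == ""] <- NA_character_
  genotype_matrix(calls, sites)
}

#' Write a truth panel as TSV (line, chrom, pos, DP-allele dosage)
#' @param panel a `truth_panel`
#' @param path file path
#' @return `path`, invisibly
#' @export
write_truth_tsv <- function(panel, path) {
  df <- data.frame(line = rep(rownames(panel$geno), ncol(panel$geno)),
                   chrom = rep(panel$map$sites$chrom,
                               each = nrow(panel$geno)),
                   pos = rep(panel$map$sites$pos, each = nrow(panel$geno)),
                   dp_dosage = as.vector(panel$geno))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write / read a genome map as TSV
#' @param map a `genome_map`
#' @param path file path
#' @return `path` invisibly (write); a `genome_map` (read)
#' @export
write_genome_map_tsv <- function(map, path) {
  chrom_df <- map$chromosomes
  sites <- map$sites[, c("chrom", "pos", "rp_allele", "dp_allele")]
  sites$length_bp <- chrom_df$length_bp[match(sites$chrom, chrom_df$chrom)]
  sites$length_cM <- chrom_df$length_cM[match(sites$chrom, chrom_df$chrom)]
  utils::write.table(sites, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_genome_map_tsv
#' @export
read_genome_map_tsv <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          colClasses = c(chrom = "character"))
  chroms <- unique(df[, c("chrom", "length_bp", "length_cM")])
  rownames(chroms) <- NULL
  genome_map(chroms, df[, c("chrom", "pos", "rp_allele", "dp_allele")])
}

#' Write segments as BED (0-based half-open)
#'
#' Columns: chrom, start, end, name (`sample|code`), score (`n_snps`).
#'
#' @param seg data.frame from [segments()]
#' @param path output file
#' @return `path`, invisibly
#' @export
write_bed <- function(seg, path) {
  bed <- data.frame(chrom = seg$chrom, start = seg$start, end = seg$end,
                    name = paste(seg$sample, seg$code, sep = "|"),
                    score = seg$n_snps)
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Default run configuration
#'
#' The full set of recognized configuration keys with their default values:
#' simulation design (lines, pedigree, genome), read model, caller and filter
#' thresholds, window scan and tree parameters. [read_run_config()] starts
#' from these defaults and overrides the keys present in the file.
#'
#' @return named list of configuration values
#' @export
run_config_defaults <- function() {
  list(seed = 1L, n_lines = 100L, n_backcrosses = 1L,
       n_selfing_generations = 4L, n_sites = 2000L, n_chrom = 12L,
       chrom_length_bp = 30e6, chrom_length_cM = 150,
       mean_depth = 10, depth_dispersion = 2, base_error_rate = 0.005,
       site_dropout_rate = 0.1, quality_of_good_base = 30L,
       min_site_reads = 3L, hom_min_major_reads = 3L,
       hom_min_base_quality = 20L, het_min_reads_per_allele = 2L,
       het_min_allele_fraction = 0.20, het_min_two_allele_fraction = 0.90,
       discovery_min_reads = 5L, discovery_min_sample_fraction = 0.50,
       max_missing_initial = 0.80, required_allele_number = 2L,
       min_genotype_classes = 2L, min_maf = 0.10,
       max_site_heterozygosity = 0.10, max_missing_lmd = 0.50,
       window_snps = 10L, step_snps = 5L, sweep_k_sd = 3.0,
       min_shared = 30L, n_groups = 2L)
}

#' Read / write the run configuration (YAML key-value file)
#'
#' Unknown keys are rejected; omitted keys take their documented defaults.
#'
#' @param path YAML file
#' @return named list of configuration values
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  defs <- run_config_defaults()
  unknown <- setdiff(names(cfg), names(defs))
  if (length(unknown))
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
  utils::modifyList(defs, cfg)
}

#' @rdname read_run_config
#' @param cfg named list of configuration values
#' @export
write_run_config <- function(cfg, path) {
  yaml::write_yaml(cfg, path)
  invisible(path)
}
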