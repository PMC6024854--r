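# Brute-force oracle for the genotype-calling rules: a literal transcription
# of the printed criteria, kept independent of the package implementation.
# (1) A site needs at least `min_site` reads. (2) Heterozygote: at least two
# reads supporting each of at least two different alleles; each of the two
# read types separately comprises more than 20% of the reads at the site;
# the two together comprise at least 90%. (3) Homozygote: at least three
# reads supporting the major allele. Ties go to the alphabetically first
# base.
oracle_call_genotype <- function(counts, min_site = 3, hom_major = 3,
                                 het_each = 2, het_frac = 0.2,
                                 het_two_frac = 0.9) {
  bases <- c("A", "C", "G", "T")
  tot <- sum(counts)
  if (tot < min_site)
    return(list(state = "MISSING", alleles = character(0)))
  cand <- which(counts >= het_each)
  if (length(cand) >= 2) {
    ord <- cand[order(-counts[cand], cand)]
    a <- ord[1]; b <- ord[2]
    if (counts[a] / tot > het_frac && counts[b] / tot > het_frac &&
        (counts[a] + counts[b]) / tot >= het_two_frac)
      return(list(state = "HET", alleles = bases[sort(c(a, b))]))
  }
  if (max(counts) >= hom_major)
    return(list(state = "HOM", alleles = bases[which.max(counts)]))
  list(state = "MISSING", alleles = character(0))
}

# a tiny deterministic genome map for unit tests
toy_map <- function(n_per_chrom = c(5L, 5L), length_bp = 1e6,
                    length_cM = 100) {
  chroms <- data.frame(chrom = sprintf("chr%d", seq_along(n_per_chrom)),
                       length_bp = length_bp, length_cM = length_cM)
  sites <- do.call(rbind, lapply(seq_along(n_per_chrom), function(i)
    data.frame(chrom = chroms$chrom[i],
               pos = as.integer(seq(1e4, by = 1e4,
                                    length.out = n_per_chrom[i])),
               rp_allele = "A", dp_allele = "G")))
  genome_map(chroms, sites)
}

# genotype matrix built from explicit per-site call vectors (samples in rows)
calls_matrix <- function(..., chrom = NULL) {
  cols <- list(...)
  calls <- do.call(cbind, cols)
  ns <- ncol(calls)
  if (is.null(chrom)) chrom <- rep("chr1", ns)
  sites <- data.frame(chrom = chrom, pos = seq_len(ns) * 1000L)
  genotype_matrix(calls, sites)
}

# the ten-site filter fixture: eight sites each engineered to be removed at a
# known cascade stage plus two clean survivors; 20 samples.
filter_fixture <- function() {
  s <- function(...) {
    x <- c(...)
    stopifnot(length(x) == 20L)
    x
  }
  M <- NA_character_
  cols <- list(
    fail_missing  = s(rep(M, 17), "A/A", "A/A", "C/C"),
    fail_monomorphic = s(rep("A/A", 20)),
    fail_triallelic  = s(rep("A/A", 10), rep("C/C", 6), rep("G/G", 4)),
    fail_one_class   = s(rep("A/C", 20)),
    fail_maf_hom     = s(rep("A/A", 19), "C/C"),
    fail_maf_het     = s(rep("A/A", 18), "A/C", "A/C"),
    fail_het         = s(rep("A/A", 14), rep("C/C", 3), rep("A/C", 3)),
    fail_lmd         = s(rep(M, 12), rep("A/A", 5), rep("C/C", 3)),
    pass_1           = s(rep("A/A", 13), rep("C/C", 5), "A/C", M),
    pass_2           = s(rep("A/A", 10), rep("G/G", 8), M, M))
  calls <- do.call(cbind, cols)
  rownames(calls) <- sprintf("S%02d", 1:20)
  sites <- data.frame(chrom = "chr1", pos = seq_len(10L) * 1000L,
                      name = names(cols))
  genotype_matrix(calls, sites)
}

# classified matrix built from explicit code vectors (one per site)
codes_matrix <- function(codes, chrom = NULL, pos = NULL,
                         samples = NULL) {
  codes <- as.matrix(codes)
  if (is.null(samples)) samples <- sprintf("S%02d", seq_len(nrow(codes)))
  rownames(codes) <- samples
  ns <- ncol(codes)
  if (is.null(chrom)) chrom <- rep("chr1", ns)
  if (is.null(pos)) pos <- seq_len(ns) * 1000L
  structure(list(codes = codes,
                 sites = data.frame(chrom = chrom, pos = pos),
                 samples = samples, non_parental = 0L),
            class = "classified_matrix")
}

# tiny synthetic annotation reference: a 3 kb chromosome with one plus-strand
# two-exon gene and one minus-strand single-exon gene; written as FASTA +
# GFF3 temp files. The plus gene's first CDS codon region contains GCA.
annotation_fixture <- function(dir = tempfile("annofix")) {
  if (!dir.exists(dir)) dir.create(dir)
  set.seed(424242)
  bases <- c("A", "C", "G", "T")
  seqv <- sample(bases, 3000, replace = TRUE)
  # plus-strand gene: CDS1 1051..1200, intron, CDS2 1301..1450
  seqv[1051:1053] <- c("A", "T", "G")
  seqv[1054:1056] <- c("G", "C", "A")          # Ala codon
  # avoid premature stops in the spliced CDS: fill with a stop-free pattern
  seqv[1057:1200] <- rep(c("G", "C", "T"), length.out = 144)
  seqv[1301:1447] <- rep(c("A", "C", "T"), length.out = 147)
  seqv[1448:1450] <- c("T", "A", "A")          # stop
  # minus-strand gene: CDS 2101..2400 (translated from 2400 down)
  seqv[2398:2400] <- c("C", "A", "T")          # revcomp ATG
  seqv[2101:2397] <- rep(c("A", "G", "C"), length.out = 297)
  seqv[2101:2103] <- c("T", "T", "A")          # revcomp TAA stop
  genome <- Biostrings::DNAStringSet(paste(seqv, collapse = ""))
  names(genome) <- "chr1"
  fa <- file.path(dir, "ref_synthetic.fa")
  Biostrings::writeXStringSet(genome, fa)
  gff <- file.path(dir, "genes_synthetic.gff3")
  lines <- c(
    "##gff-version 3",
    "chr1\ttest\tgene\t1001\t1600\t.\t+\t.\tID=LOC_A",
    "chr1\ttest\tmRNA\t1001\t1600\t.\t+\t.\tID=LOC_A.1;Parent=LOC_A",
    "chr1\ttest\tfive_prime_UTR\t1001\t1050\t.\t+\t.\tParent=LOC_A.1",
    "chr1\ttest\tCDS\t1051\t1200\t.\t+\t0\tParent=LOC_A.1",
    "chr1\ttest\tCDS\t1301\t1450\t.\t+\t0\tParent=LOC_A.1",
    "chr1\ttest\tthree_prime_UTR\t1451\t1600\t.\t+\t.\tParent=LOC_A.1",
    "chr1\ttest\tgene\t2001\t2500\t.\t-\t.\tID=LOC_B",
    "chr1\ttest\tmRNA\t2001\t2500\t.\t-\t.\tID=LOC_B.1;Parent=LOC_B",
    "chr1\ttest\tthree_prime_UTR\t2001\t2100\t.\t-\t.\tParent=LOC_B.1",
    "chr1\ttest\tCDS\t2101\t2400\t.\t-\t0\tParent=LOC_B.1",
    "chr1\ttest\tfive_prime_UTR\t2401\t2500\t.\t-\t.\tParent=LOC_B.1")
  writeLines(lines, gff)
  list(fasta = fa, gff3 = gff, genome = genome)
}

# whole-protein translation oracle for codon effects: substitute the variant
# into the genome, splice the transcript's CDS from the GFF intervals,
# translate the entire protein, and diff against the reference protein.
oracle_codon_effect <- function(chrom, pos, ref, alt, transcript_id, models,
                                genome) {
  f <- models$features
  cds <- f[f$transcript_id == transcript_id & f$type == "CDS", ]
  cds <- cds[order(cds$start), ]
  translate_from <- function(g) {
    pieces <- vapply(seq_len(nrow(cds)), function(i)
      as.character(Biostrings::subseq(g[[chrom]], cds$start[i],
                                      cds$end[i])), character(1))
    s <- paste(pieces, collapse = "")
    if (cds$strand[1] == "-")
      s <- as.character(
        Biostrings::reverseComplement(Biostrings::DNAString(s)))
    as.character(Biostrings::translate(Biostrings::DNAString(s)))
  }
  p_ref <- translate_from(genome)
  g2 <- genome
  chr_seq <- as.character(g2[[chrom]])
  stopifnot(substr(chr_seq, pos, pos) == ref)
  substr(chr_seq, pos, pos) <- alt
  g2 <- Biostrings::DNAStringSet(chr_seq)
  names(g2) <- chrom
  p_alt <- translate_from(g2)
  diffs <- which(strsplit(p_ref, "")[[1]] != strsplit(p_alt, "")[[1]])
  if (length(diffs) == 0L)
    list(effect = "synonymous", aa_ref = NA, aa_alt = NA)
  else
    list(effect = "non-synonymous",
         aa_ref = substr(p_ref, diffs[1], diffs[1]),
         aa_alt = substr(p_alt, diffs[1], diffs[1]))
}
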