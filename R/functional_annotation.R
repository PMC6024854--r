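# Genomic context, codon effect, and SIFT-score classification of SNPs.
#
# Gene models come from GFF3 (via rtracklayer), the reference from FASTA
# (via Biostrings). Context precedence: CDS > UTR > intron > regulatory
# (within a configurable upstream window of the TSS, strand-aware) >
# intergenic. SIFT scores are consumed from a table, never computed.

#' Read gene models from a GFF3 file
#'
#' Expects gene / mRNA / CDS (and optionally *_UTR, exon) features with
#' `ID`/`Parent` attributes. By default the longest-CDS transcript represents
#' each locus.
#'
#' @param path GFF3 file
#' @param longest_only keep only the longest-CDS transcript per locus?
#' @return object of class `gene_models`: list with `features` (data.frame:
#'   locus_id, transcript_id, type, chrom, start, end, strand) and
#'   `transcripts` (data.frame with TSS and span per transcript)
#' @export
read_gene_models <- function(path, longest_only = TRUE) {
  gr <- rtracklayer::import(path, format = "gff3")
  df <- as.data.frame(gr)
  df$seqnames <- as.character(df$seqnames)
  df$strand <- as.character(df$strand)
  type <- as.character(df$type)
  get1 <- function(x) vapply(x, function(v)
    if (length(v)) as.character(v)[1] else NA_character_, character(1))
  id <- if ("ID" %in% names(df)) as.character(df$ID) else NA_character_
  parent <- if ("Parent" %in% names(df)) get1(df$Parent)
            else rep(NA_character_, nrow(df))
  genes <- df[type == "gene", , drop = FALSE]
  gene_ids <- id[type == "gene"]
  mrna <- df[type == "mRNA", , drop = FALSE]
  mrna_ids <- id[type == "mRNA"]
  mrna_parent <- parent[type == "mRNA"]
  if (nrow(mrna) == 0L) stop("GFF3 contains no mRNA features")
  sub_types <- c("CDS", "five_prime_UTR", "three_prime_UTR", "exon")
  sub <- df[type %in% sub_types, , drop = FALSE]
  sub_type <- type[type %in% sub_types]
  sub_parent <- parent[type %in% sub_types]
  locus_of <- function(tid) mrna_parent[match(tid, mrna_ids)]
  feats <- data.frame(locus_id = locus_of(sub_parent),
                      transcript_id = sub_parent,
                      type = ifelse(sub_type %in% c("five_prime_UTR",
                                                    "three_prime_UTR"),
                                    "UTR", sub_type),
                      chrom = sub$seqnames, start = sub$start, end = sub$end,
                      strand = sub$strand)
  if (anyNA(feats$locus_id))
    stop("malformed gene model: mRNA parent missing for transcript(s) ",
         paste(unique(feats$transcript_id[is.na(feats$locus_id)]),
               collapse = ", "))
  trs <- data.frame(transcript_id = mrna_ids, locus_id = mrna_parent,
                    chrom = mrna$seqnames, start = mrna$start,
                    end = mrna$end, strand = mrna$strand)
  trs$tss <- ifelse(trs$strand == "+", trs$start, trs$end)
  cds_len <- vapply(trs$transcript_id, function(tid) {
    f <- feats[feats$transcript_id == tid & feats$type == "CDS", ]
    sum(f$end - f$start + 1L)
  }, numeric(1))
  trs$cds_length <- cds_len
  if (any(cds_len %% 3L != 0L))
    stop("CDS length not divisible by 3 for transcript(s): ",
         paste(trs$transcript_id[cds_len %% 3L != 0L], collapse = ", "))
  if (longest_only) {
    keep_t <- unlist(lapply(split(trs, trs$locus_id), function(g)
      g$transcript_id[which.max(g$cds_length)]))
    trs <- trs[trs$transcript_id %in% keep_t, , drop = FALSE]
    feats <- feats[feats$transcript_id %in% keep_t, , drop = FALSE]
  }
  rownames(trs) <- rownames(feats) <- NULL
  structure(list(features = feats, transcripts = trs,
                 gene_ids = gene_ids), class = "gene_models")
}

#' Locate SNPs in their genomic context
#'
#' Assigns each SNP a primary context by precedence CDS > UTR > intron >
#' regulatory > intergenic. "Intron" means inside a transcript span but in no
#' CDS/UTR interval; "regulatory" means within `upstream_bp` of a
#' transcription start site, on the gene-proximal (upstream) side,
#' strand-aware. All transcripts overlapping a SNP are reported in
#' `all_loci`.
#'
#' @param snps data.frame with `chrom`, `pos`
#' @param models a `gene_models`
#' @param upstream_bp regulatory window upstream of the TSS (default 1000)
#' @return data.frame: `chrom`, `pos`, `context`, `locus_id`,
#'   `transcript_id`, `all_loci` (comma-separated)
#' @export
locate_snps <- function(snps, models, upstream_bp = 1000L) {
  stopifnot(inherits(models, "gene_models"))
  trs <- models$transcripts
  feats <- models$features
  n <- nrow(snps)
  context <- rep("intergenic", n)
  locus <- rep(NA_character_, n)
  transcript <- rep(NA_character_, n)
  all_loci <- rep(NA_character_, n)
  lev <- union(unique(snps$chrom), unique(trs$chrom))
  snp_gr <- GenomicRanges::GRanges(factor(snps$chrom, levels = lev),
                                   IRanges::IRanges(snps$pos, snps$pos))
  tr_gr <- GenomicRanges::GRanges(factor(trs$chrom, levels = lev),
                                  IRanges::IRanges(trs$start, trs$end))
  ov <- GenomicRanges::findOverlaps(snp_gr, tr_gr)
  ov_snp <- S4Vectors::queryHits(ov); ov_tr <- S4Vectors::subjectHits(ov)
  prec <- c(CDS = 1, UTR = 2, intron = 3)
  for (i in unique(ov_snp)) {
    hits <- ov_tr[ov_snp == i]
    best <- NULL
    for (h in hits) {
      tid <- trs$transcript_id[h]
      f <- feats[feats$transcript_id == tid, , drop = FALSE]
      inside <- f$start <= snps$pos[i] & snps$pos[i] <= f$end
      ctx <- if (any(inside & f$type == "CDS")) "CDS"
             else if (any(inside & f$type == "UTR")) "UTR"
             else "intron"
      if (is.null(best) || prec[ctx] < prec[best$ctx])
        best <- list(ctx = ctx, tid = tid, locus = trs$locus_id[h])
    }
    context[i] <- best$ctx
    transcript[i] <- best$tid
    locus[i] <- best$locus
    all_loci[i] <- paste(unique(trs$locus_id[hits]), collapse = ",")
  }
  # regulatory: upstream window of a TSS, strand-aware, for still-intergenic
  reg_start <- ifelse(trs$strand == "+", trs$tss - upstream_bp, trs$tss + 1L)
  reg_end <- ifelse(trs$strand == "+", trs$tss - 1L, trs$tss + upstream_bp)
  reg_gr <- GenomicRanges::GRanges(factor(trs$chrom, levels = lev),
                                   IRanges::IRanges(pmax(reg_start, 1L),
                                                    pmax(reg_end, 1L)))
  ovr <- GenomicRanges::findOverlaps(snp_gr, reg_gr)
  for (k in seq_along(ovr)) {
    i <- S4Vectors::queryHits(ovr)[k]; h <- S4Vectors::subjectHits(ovr)[k]
    if (context[i] != "intergenic") next
    context[i] <- "regulatory"
    transcript[i] <- trs$transcript_id[h]
    locus[i] <- trs$locus_id[h]
  }
  data.frame(chrom = snps$chrom, pos = snps$pos, context = context,
             locus_id = locus, transcript_id = transcript,
             all_loci = all_loci)
}

# spliced CDS of a transcript on the coding strand, plus the mapping from
# genomic position to CDS position
spliced_cds <- function(tid, models, genome) {
  f <- models$features
  cds <- f[f$transcript_id == tid & f$type == "CDS", , drop = FALSE]
  if (nrow(cds) == 0L) stop("transcript ", tid, " has no CDS")
  cds <- cds[order(cds$start), , drop = FALSE]
  chrom <- cds$chrom[1]
  seqs <- lapply(seq_len(nrow(cds)), function(i)
    Biostrings::subseq(genome[[chrom]], cds$start[i], cds$end[i]))
  plus <- paste0(vapply(seqs, as.character, character(1)), collapse = "")
  gpos <- unlist(lapply(seq_len(nrow(cds)), function(i)
    seq.int(cds$start[i], cds$end[i])))
  strand <- cds$strand[1]
  if (strand == "-") {
    seq_cds <- as.character(
      Biostrings::reverseComplement(Biostrings::DNAString(plus)))
    gpos <- rev(gpos)
  } else {
    seq_cds <- plus
  }
  list(seq = seq_cds, gpos = gpos, strand = strand, chrom = chrom)
}

#' Codon effect of a coding SNP
#'
#' Splices the transcript's CDS (reverse-complemented for minus-strand
#' genes), substitutes the alternate allele, and translates the affected
#' codon with the standard nuclear code. The SNP is synonymous iff the amino
#' acid is unchanged; stop gain/loss is reported as non-synonymous with a
#' flag.
#'
#' @param chrom,pos SNP coordinate (1-based)
#' @param ref,alt reference and alternate allele on the forward genomic
#'   strand; `ref` must match the reference sequence at `pos`
#' @param transcript_id transcript to annotate against
#' @param models a `gene_models`
#' @param genome a [Biostrings::DNAStringSet] keyed by chromosome
#' @return list: `effect` ("synonymous"/"non-synonymous"), `aa_ref`,
#'   `aa_alt`, `codon_index`, `stop_change`
#' @export
codon_effect <- function(chrom, pos, ref, alt, transcript_id, models,
                         genome) {
  sc <- spliced_cds(transcript_id, models, genome)
  if (sc$chrom != chrom) stop("SNP chromosome does not match transcript")
  cds_pos <- match(pos, sc$gpos)
  if (is.na(cds_pos)) stop("position ", pos, " is not in the CDS of ",
                           transcript_id)
  genomic_base <- as.character(Biostrings::subseq(genome[[chrom]], pos, pos))
  if (genomic_base != ref)
    stop("reference allele mismatch at ", chrom, ":", pos, " (reference has ",
         genomic_base, ", got ", ref, ")")
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  ref_c <- if (sc$strand == "-") comp[[ref]] else ref
  alt_c <- if (sc$strand == "-") comp[[alt]] else alt
  stopifnot(substr(sc$seq, cds_pos, cds_pos) == ref_c)
  codon_idx <- (cds_pos - 1L) %/% 3L + 1L
  off <- (cds_pos - 1L) %% 3L + 1L
  codon <- substr(sc$seq, (codon_idx - 1L) * 3L + 1L, codon_idx * 3L)
  codon_alt <- codon
  substr(codon_alt, off, off) <- alt_c
  aa_ref <- as.character(Biostrings::translate(Biostrings::DNAString(codon)))
  aa_alt <- as.character(
    Biostrings::translate(Biostrings::DNAString(codon_alt)))
  list(effect = if (aa_ref == aa_alt) "synonymous" else "non-synonymous",
       aa_ref = aa_ref, aa_alt = aa_alt, codon_index = codon_idx,
       stop_change = xor(aa_ref == "*", aa_alt == "*"))
}

#' Annotate a set of SNPs
#'
#' Runs [locate_snps()] and, for CDS SNPs, [codon_effect()]; returns one
#' annotation record per SNP.
#'
#' @param snps data.frame with `chrom`, `pos`, `ref`, `alt`
#' @param models a `gene_models`
#' @param genome a [Biostrings::DNAStringSet]
#' @param upstream_bp regulatory window (see [locate_snps()])
#' @return data.frame of annotation records: context, effect, aa change,
#'   locus id; `sift_class`/`highly_detrimental` columns initialized to `NA`
#'   (fill with [sift_classify()])
#' @export
annotate_snps <- function(snps, models, genome, upstream_bp = 1000L) {
  loc <- locate_snps(snps, models, upstream_bp)
  n <- nrow(snps)
  effect <- rep(NA_character_, n)
  aa_ref <- rep(NA_character_, n); aa_alt <- rep(NA_character_, n)
  stop_change <- rep(NA, n)
  for (i in which(loc$context == "CDS")) {
    ce <- codon_effect(snps$chrom[i], snps$pos[i], snps$ref[i], snps$alt[i],
                       loc$transcript_id[i], models, genome)
    effect[i] <- ce$effect
    aa_ref[i] <- ce$aa_ref; aa_alt[i] <- ce$aa_alt
    stop_change[i] <- ce$stop_change
  }
  cbind(loc[, c("chrom", "pos", "context", "locus_id", "transcript_id",
                "all_loci")],
        data.frame(ref = snps$ref, alt = snps$alt, effect = effect,
                   aa_ref = aa_ref, aa_alt = aa_alt,
                   stop_change = stop_change,
                   sift_score = NA_real_, sift_class = NA_character_,
                   highly_detrimental = NA))
}

#' Classify non-synonymous SNPs by SIFT score
#'
#' A non-synonymous substitution is `deleterious` if its SIFT score is at or
#' below `threshold` (inclusive), otherwise `tolerated`; a score of exactly
#' 0.00 is additionally flagged `highly_detrimental`. Records without a
#' matching score keep `NA` (counted in a warning). Duplicate conflicting
#' scores for one SNP are an error.
#'
#' @param records annotation data.frame from [annotate_snps()]
#' @param sift data.frame with `locus_id`, `pos`, `score` in `[0, 1]`
#' @param threshold deleterious bound (default 0.05, inclusive)
#' @return `records` with `sift_score`, `sift_class` and
#'   `highly_detrimental` filled for non-synonymous rows
#' @export
sift_classify <- function(records, sift, threshold = 0.05) {
  stopifnot(all(c("locus_id", "pos", "score") %in% names(sift)))
  if (any(sift$score < 0 | sift$score > 1))
    stop("SIFT scores must be in [0, 1]")
  key <- paste(sift$locus_id, sift$pos)
  dup <- duplicated(key)
  if (any(dup)) {
    conflict <- vapply(unique(key[dup]), function(k)
      length(unique(sift$score[key == k])) > 1L, logical(1))
    if (any(conflict))
      stop("conflicting duplicate SIFT scores for: ",
           paste(unique(key[dup])[conflict], collapse = "; "))
    sift <- sift[!dup, , drop = FALSE]
    key <- key[!dup]
  }
  ns <- which(!is.na(records$effect) & records$effect == "non-synonymous")
  rkey <- paste(records$locus_id, records$pos)[ns]
  hit <- match(rkey, key)
  n_missing <- sum(is.na(hit))
  if (n_missing > 0)
    warning(n_missing, " non-synonymous SNP(s) have no SIFT score")
  sc <- sift$score[hit]
  records$sift_score[ns] <- sc
  records$sift_class[ns] <- ifelse(is.na(sc), NA_character_,
                                   ifelse(sc <= threshold, "deleterious",
                                          "tolerated"))
  records$highly_detrimental[ns] <- ifelse(is.na(sc), NA, sc == 0)
  records
}

#' Per-locus deleterious-SNP counts and context tallies
#'
#' @param records annotation data.frame after [sift_classify()]
#' @return list with `per_locus` (data.frame: locus_id, n_deleterious) and
#'   `context_proportions` (named vector over contexts, summing to 1)
#' @export
per_locus_summary <- function(records) {
  del <- records[!is.na(records$sift_class) &
                 records$sift_class == "deleterious", , drop = FALSE]
  per_locus <- if (nrow(del) == 0L)
    data.frame(locus_id = character(0), n_deleterious = integer(0))
  else {
    tab <- table(del$locus_id)
    data.frame(locus_id = names(tab), n_deleterious = as.integer(tab),
               row.names = NULL)
  }
  ctx <- table(factor(records$context,
                      levels = c("CDS", "UTR", "intron", "regulatory",
                                 "intergenic")))
  props <- stats::setNames(as.numeric(ctx) / sum(ctx), names(ctx))
  list(per_locus = per_locus, context_proportions = props)
}
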