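# Genomic context, codon effects, SIFT classification.

fx <- annotation_fixture()
models <- read_gene_models(fx$gff3)
genome <- Biostrings::readDNAStringSet(fx$fasta)
names(genome) <- sub(" .*", "", names(genome))

test_that("gene models load with spliced CDS lengths divisible by 3", {
  expect_identical(sort(models$transcripts$locus_id), c("LOC_A", "LOC_B"))
  expect_identical(models$transcripts$cds_length, c(300, 300))
})

test_that("context assignment follows the precedence", {
  snps <- data.frame(chrom = "chr1",
                     pos = c(1100L,   # CDS exon 1 of LOC_A
                             1020L,   # 5' UTR
                             1250L,   # intron
                             700L,    # 500 bp upstream of + strand TSS
                             2650L,   # within 1 kb downstream... upstream of
                                      # the minus-strand TSS at 2500
                             2900L))  # still in the minus regulatory window
  loc <- locate_snps(snps, models)
  expect_identical(loc$context,
                   c("CDS", "UTR", "intron", "regulatory", "regulatory",
                     "regulatory"))
  snps2 <- data.frame(chrom = "chr9", pos = 500L)
  expect_identical(locate_snps(snps2, models)$context, "intergenic")
  # between the genes, outside both regulatory windows
  loc3 <- locate_snps(data.frame(chrom = "chr1", pos = 1800L), models)
  expect_identical(loc3$context, "intergenic")
})

test_that("GCA codon substitutions classify as printed", {
  # codon 2 of LOC_A is GCA (Ala) at 1054-1056
  ce <- codon_effect("chr1", 1054L, "G", "A", "LOC_A.1", models, genome)
  expect_identical(ce$effect, "non-synonymous")
  expect_identical(ce$aa_ref, "A")   # Ala
  expect_identical(ce$aa_alt, "T")   # Thr
  ce2 <- codon_effect("chr1", 1056L, "A", "G", "LOC_A.1", models, genome)
  expect_identical(ce2$effect, "synonymous")
  expect_identical(ce2$aa_ref, "A")
})

test_that("reference-allele mismatch errors with the position", {
  expect_error(codon_effect("chr1", 1054L, "T", "A", "LOC_A.1", models,
                            genome), "1054")
})

test_that("codon_effect agrees with the whole-protein oracle on both strands", {
  set.seed(60)
  cds_pos <- list(LOC_A.1 = c(1051:1200, 1301:1450),
                  LOC_B.1 = 2101:2400)
  for (tid in names(cds_pos)) {
    pos_pool <- sample(cds_pos[[tid]], 40)
    for (pos in pos_pool) {
      ref <- as.character(Biostrings::subseq(genome[["chr1"]], pos, pos))
      alt <- sample(setdiff(c("A", "C", "G", "T"), ref), 1)
      got <- codon_effect("chr1", pos, ref, alt, tid, models, genome)
      want <- oracle_codon_effect("chr1", pos, ref, alt, tid, models, genome)
      expect_identical(got$effect, want$effect,
                       info = sprintf("%s pos %d %s>%s", tid, pos, ref, alt))
      if (want$effect == "non-synonymous") {
        expect_identical(got$aa_ref, want$aa_ref)
        expect_identical(got$aa_alt, want$aa_alt)
      }
    }
  }
})

test_that("SIFT classification applies the inclusive 0.05 bound", {
  rec <- data.frame(chrom = "chr1", pos = c(10L, 20L, 30L, 40L),
                    context = "CDS", locus_id = "LOC_X",
                    transcript_id = "LOC_X.1", all_loci = "LOC_X",
                    ref = "A", alt = "G",
                    effect = c("non-synonymous", "non-synonymous",
                               "non-synonymous", "synonymous"),
                    aa_ref = "A", aa_alt = "T", stop_change = FALSE,
                    sift_score = NA_real_, sift_class = NA_character_,
                    highly_detrimental = NA)
  sift <- data.frame(locus_id = "LOC_X", pos = c(10L, 20L, 30L),
                     score = c(0.05, 0.051, 0.00))
  out <- sift_classify(rec, sift)
  expect_identical(out$sift_class[1:3],
                   c("deleterious", "tolerated", "deleterious"))
  expect_identical(out$highly_detrimental[1:3], c(FALSE, FALSE, TRUE))
  expect_true(is.na(out$sift_class[4]))      # synonymous left NA
  # idempotent and permutation-invariant
  out2 <- sift_classify(out, sift[c(3, 1, 2), ])
  expect_identical(out2$sift_class, out$sift_class)
  # missing score warns; conflicting duplicates error
  rec2 <- rec; rec2$pos[1] <- 99L
  expect_warning(sift_classify(rec2, sift), "no SIFT score")
  bad <- rbind(sift, data.frame(locus_id = "LOC_X", pos = 10L, score = 0.9))
  expect_error(sift_classify(rec, bad), "conflicting")
})

test_that("per-locus summary counts deleterious SNPs and tallies contexts", {
  rec <- data.frame(chrom = "chr1", pos = seq_len(10L),
                    context = c(rep("CDS", 7), "intron", "regulatory",
                                "intergenic"),
                    locus_id = c(rep("L1", 1), rep("L2", 2), rep("L3", 4),
                                 "L4", "L5", NA),
                    transcript_id = NA, all_loci = NA, ref = "A", alt = "G",
                    effect = c(rep("non-synonymous", 7), rep(NA, 3)),
                    aa_ref = NA, aa_alt = NA, stop_change = FALSE,
                    sift_score = c(rep(0.01, 7), rep(NA, 3)),
                    sift_class = c(rep("deleterious", 7), rep(NA, 3)),
                    highly_detrimental = FALSE)
  s <- per_locus_summary(rec)
  expect_identical(s$per_locus$n_deleterious,
                   c(1L, 2L, 4L))
  expect_identical(range(s$per_locus$n_deleterious), c(1L, 4L))
  expect_equal(sum(s$context_proportions), 1)
  # no deleterious SNPs: empty summary
  rec$sift_class <- NA_character_
  expect_identical(nrow(per_locus_summary(rec)$per_locus), 0L)
})

test_that("annotate_snps combines location and codon effect", {
  snps <- data.frame(chrom = "chr1", pos = c(1054L, 1250L),
                     ref = c("G", as.character(
                       Biostrings::subseq(genome[["chr1"]], 1250, 1250))),
                     alt = c("A", "T"))
  rec <- annotate_snps(snps, models, genome)
  expect_identical(rec$context, c("CDS", "intron"))
  expect_identical(rec$effect[1], "non-synonymous")
  expect_true(is.na(rec$effect[2]))
})
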