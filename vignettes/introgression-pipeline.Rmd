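---
title: "SNP-typing early-backcross introgression panels: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{SNP-typing early-backcross introgression panels: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
set.seed(1)
```

`introgressr` implements a genotyping-by-sequencing (GBS) SNP-typing pipeline
for early-backcross introgression-line (IL) panels: populations built by
crossing donor cultivars to a shared recurrent parent (RP), backcrossing once,
and selfing to near-fixation (BC~1~F~5~). This vignette documents the models
behind each stage, the parameters that matter, and the design choices made
where the procedure was genuinely open.

```{r setup, message = FALSE}
library(introgressr)
```

## The breeding-design simulator

The simulator is the package's test bed: it generates panels with known truth
so every downstream stage can be validated quantitatively.

**Genome and meiosis.** A `genome_map()` holds chromosomes (physical length in
bp, genetic length in cM) and biallelic SNP sites, each labelled with the RP
and donor-parent (DP) allele; genetic positions are linear interpolations of
cM onto bp. Meiosis (`simulate_gamete()`) draws a Poisson number of crossovers
per chromosome with mean `length_cM / 100` and places them uniformly on the
genetic map — no crossover interference, so two-point recombination follows
the Haldane map function, `c = (1 - e^{-2d/100}) / 2` for map distance `d` cM.
The default map (12 chromosomes of 150 cM, 2,000 sites in total) is a
desk-scale rice-like frame; all sizes are configurable.

**Pedigree.** `simulate_panel()` derives each line independently: F~1~ =
RP x DP, `n_backcrosses` crosses to the RP (default 1), then
`n_selfing_generations` single-seed-descent selfings (default 4, giving
BC~1~F~5~). The neutral expectations, used as parameter-recovery tests, are a
RP-allele frequency of `1 - (1/2)^(1+n_backcrosses) = 0.75` and a residual
heterozygosity of `0.5 * (1/2)^4 = 0.03125`.

**Selection.** Stress screening is emulated by per-locus rejection sampling:
a selection locus (`require_donor_allele` or `require_donor_homozygote`, with
a number of `rounds`) is enforced at the last `rounds` generation transitions
of each pedigree; offspring failing the predicate are redrawn. A parent that
cannot produce a passing offspring (it lost the donor allele) aborts the line,
which restarts from the F~1~ — the analogue of a discarded plant in the
screening nursery. A configuration no pedigree can satisfy (for example a
donor homozygote demanded in a backcross offspring) raises an error once the
restart cap is exhausted.

**Read counts.** `simulate_read_counts()` emulates the tunable-GBS depth
profile: per sample and site, depth is negative binomial with mean
`mean_depth` (default 10) and size `depth_dispersion` (default 2 — strongly
over-dispersed, as reduced-representation libraries are), with an additional
`site_dropout_rate` (default 0.1) probability of zero coverage mimicking
restriction-site absence. Each read's base is drawn from the true genotype
(1/2–1/2 for heterozygotes) and miscalled to a uniformly chosen other base
with probability `base_error_rate` (default 0.005, i.e. roughly a Q23–Q30
post-filter error regime). Simulated bases carry a single PHRED quality
(default 30). What the generator does **not** emulate: alignment artefacts,
paralogy-driven heterozygote excess, index hopping, depth correlation between
neighbouring sites, and allele-specific amplification bias. Tests passing on
simulated data therefore validate the pipeline's logic and its statistical
behaviour under idealized noise, not robustness to every real-data artefact.

**The multi-donor design.** `simulate_design_panel()` builds the full
crossing structure: one shared RP crossed to 11 donors, 8 lines per donor by
default. Two choices here deserve explanation, both made because the naive
alternative demonstrably destroys structure every real panel shows:

* *Donor haplotypes are private.* On a shared biallelic frame, "distinct
  donors" must differ in which sites carry the DP allele. The default
  partitions sites round-robin among donors, so each donor is polymorphic
  against the RP at its own share — mirroring GBS panels, where most SNPs are
  discovered as polymorphisms private to one donor x RP cross. (A `"random"`
  mode with a shared density is available; with it, unrelated donors end up
  mutually closer than to their own ILs and cluster together in the tree,
  which no panel of unrelated cultivars shows.)
* *Lines share backcross ancestry.* Sub-populations are really grown from
  bulked seed of a small number of BC~1~ plants, so lines within a
  sub-population share the BC~1~'s donor complement. The generator derives
  each sub-population's lines from `n_founders` shared BC~1~ plants (default
  1). With fully independent pedigrees the within-donor segregation variance
  of BC~1~F~5~ lines exceeds the between-donor separation (measured allele-
  sharing dissimilarities 0.19 within vs 0.22 between) and no clustering
  method can recover the lineages; the shared founder restores the
  sub-population signature that diversity trees actually show.

## Genotype calling

`call_genotype()` implements read-support rules on quality-passing counts
(bases below PHRED 20 are masked):

1. fewer than 3 reads at the site: missing;
2. heterozygote first: among alleles with ≥ 2 reads, take the two best
   supported; each must exceed 20% of the site's reads (strict) and together
   reach 90% (inclusive);
3. otherwise homozygote if the major allele has ≥ 3 reads;
4. otherwise missing.

The heterozygote test runs first because it is the more specific pattern and
its 90% two-allele rule already guards against noise; a 7/3 read split
therefore calls heterozygous, not homozygous. Major-allele ties are broken
toward the alphabetically first base and flagged `ambiguous`. Fraction
comparisons carry a 1e-9 epsilon so that exact boundary fractions (e.g. a
minor allele at exactly 20%) behave as printed. The test suite holds a
brute-force transcription of these rules and checks equivalence exhaustively
over every count configuration of total depth ≤ 12.

Site discovery (`discover_sites()`) retains sites with ≥ 5 reads in at least
50% of samples (both bounds inclusive) that are polymorphic across the called
genotypes.

## The filter cascade and LMD50

`apply_cascade()` applies six per-site predicates in a fixed order: missing
rate ≤ 0.80; exactly 2 alleles; ≥ 2 genotype classes; minor allele frequency
≥ 0.10; heterozygous-call fraction ≤ 0.10 (inclusive — the conventional
reading of a "0–10%" band); and finally the low-missing-data rule, missing
rate ≤ 0.50, which defines the LMD50 set. Allele frequencies are
genotype-derived (a homozygote contributes two copies, a heterozygote one of
each), not read-derived. Because all predicates are per-site functions of the
same matrix, the survivor set is order-independent; the attrition table
reports each site at its first failing stage. `apply_cascade_by_population()`
filters each sub-population (its lines plus both parents) separately and
unions the survivors — the mode to use for multi-donor panels, where
donor-private SNPs are monomorphic in the other ten sub-populations and would
fail a pooled MAF filter.

## Introgression profiling

`classify()` codes each call against the parent key (RP-homozygote,
DP-homozygote, heterozygote, missing) at sites where both parents were called
homozygous for different alleles. Calls showing a non-parental allele are set
missing and counted separately, since the three-category display has no
fourth class. `sample_composition()` reports proportions over all sites and
over non-missing calls (both denominators, as panel summaries are usually
shown). `allele_frequency_track()` computes per-site RP-allele frequency
`(2*RP_HOM + HET) / (2*non-missing)`; `window_scan()` averages it in sliding
windows of 10 SNPs advancing by 5 (unweighted over sites; trailing windows
with ≥ 5 SNPs are kept and flagged partial rather than silently dropped).
`sweep_candidates()` flags windows whose DP-allele frequency exceeds the
genome-wide window mean by more than 3 window SDs and merges adjacent flags
into intervals — a deliberately simple outlier rule (the threshold is a
parameter) rather than a formal sweep statistic, which is out of scope.
`segments()` emits per-sample BED intervals of consecutive same-code SNPs,
optionally bridging interior missing calls flanked by the same code.

## Functional annotation

`locate_snps()` assigns a primary genomic context with precedence CDS > UTR >
intron > regulatory > intergenic. "Regulatory" is defined as within 1 kb
upstream of a transcription start, strand-aware — a common promoter
heuristic, configurable, adopted because no operational definition is
standard. Multi-transcript loci are annotated against the longest-CDS
transcript by default. `codon_effect()` splices the CDS, substitutes the
alternate allele (reverse-complemented for minus-strand genes), and
translates the affected codon with the standard code; a whole-protein
translation oracle cross-checks it in the tests on randomized genes of both
strands. `sift_classify()` consumes a table of precomputed SIFT scores:
non-synonymous substitutions with score ≤ 0.05 (inclusive) are deleterious,
those with score exactly 0.00 additionally flagged highly detrimental. Scores
are inputs, never computed here.

## Diversity analysis

`snp_dissimilarity()` is the allele-sharing dissimilarity for codominant
data: per shared non-missing site, 1 for identical genotypes, 0.5 for a
homozygote and a heterozygote sharing an allele, 0 otherwise; pairwise
deletion with a `min_shared` floor of 30 sites (LMD50 guarantees ample
overlap). `neighbor_joining()` is the classical agglomerative algorithm
(Q-criterion joins, Studier–Keppler updates, three-point formulas for the
final star); ties in Q break toward the smallest index pair, and negative
branch lengths are clamped to zero for display with raw lengths kept in an
attribute. The implementation is validated against additive matrices (exact
recovery to 1e-9) and against an independent reference implementation.
`extract_groups(tree, k)` cuts the `k - 1` longest internal branches and
reads groups off the connected components; `k = 1` and `k = n` are handled as
the obvious limits since an unrooted binary tree has only `n - 3` internal
branches.

## A worked desk-scale run

```{r pipeline, eval = FALSE}
cfg <- run_config_defaults()
cfg$n_lines <- 40; cfg$n_sites <- 600; cfg$n_chrom <- 6; cfg$seed <- 42
res <- run_pipeline(cfg, out_dir = tempfile("ilrun"))
head(res$composition[, c("sample", "prop_rp_hom_nm", "prop_dp_hom_nm",
                         "prop_het_nm")])
res$filtered$attrition
```

The same driver sits behind `inst/scripts/ilpipeline.R`, a thin command-line
wrapper taking `--config`, `--out` and `--seed`.

## Numerical and scale choices

Simulation-based tests run at deliberately modest sizes — panels of 40–500
lines over 300–2,000 sites, chosen so the whole suite exercises every stage
end-to-end in minutes on one core while keeping Monte-Carlo standard errors
small enough for 3-SE assertions. Stochastic checks fix their seeds; pedigree
expectations are tested against analytic values (0.75, 0.03125) within three
standard errors estimated from the line-level spread; the sweep-recovery
check demands the selected locus inside a flagged interval in at least 90% of
50 replicates. Degenerate inputs (all-missing sites, empty matrices,
single-sample cubes, chromosomes shorter than one window) return defined
results or named errors rather than propagating NaN.

## Known limitations

* The simulator's independence assumptions (between sites within a read, and
  between lines given the founders) understate the correlation structure of
  real libraries.
* The sweep rule is an outlier flag, not a test with a calibrated error rate.
* Classification requires both parents called homozygous at a site; panels
  with residually heterozygous parents lose those sites rather than imputing
  them (imputation is deliberately excluded throughout).
* Strict one-to-one lineage recovery (every group containing *all* of its
  lineage) is harder than purity: single-seed-descent segregation occasionally
  splits a sub-population across two branches of the tree even when every
  resulting group is pure.
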