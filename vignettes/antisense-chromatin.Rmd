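---
title: "Profiling chromatin architecture against nascent antisense transcription"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Profiling chromatin architecture against nascent antisense transcription}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(antisensr)
library(dplyr)
```

## The question and the procedure

Most budding-yeast genes experience nascent transcription of their antisense
strand, initiating near the 3' end and frequently running back across the
sense promoter. Because steady-state antisense transcripts are rapidly
degraded, this activity is only visible in nascent-transcription assays such
as NET-seq, which report strand-specific, base-resolution counts of engaged
RNA polymerase. `antisensr` implements a genome-wide descriptive pipeline
that asks which chromatin features track the *level* of antisense
transcription at a gene, and whether those features are distinct from the
ones tracking sense transcription.

The pipeline's stages are:

1. **Classification.** Each gene's antisense NET-seq reads are summed in a
   300 bp half-open window immediately downstream of the sense TSS,
   `[0, 300)` in transcriptional coordinates. Genes are split into five
   classes: class 1 is *count-defined* (exactly the genes with 0 or 1 read),
   and the remaining genes are rank-split into four groups of
   as-equal-as-possible size. Mixing an absolute rule for the bottom class
   with quantile splitting for the rest reproduces the canonical structure
   of this analysis (a bottom class near 24% of genes, the others near 20%).
   Tie blocks at a split boundary go entirely to the lower class, making the
   assignment deterministic and order-independent; the four class boundaries
   (minimum count per class, lower-inclusive) are retained so other
   libraries can be mapped onto the same scale.
2. **Profiling.** Any genomic signal (nucleosome occupancy, H3, H3
   modifications, factor ChIP) is averaged TSS-anchored in 10 bp bins from
   -1000 to +1500 bp per class (`metagene_profile()`), or correlated
   bin-by-bin across genes with the sense and antisense window counts using
   Spearman's rank correlation (`correlation_profile()`). Histone marks are
   divided position-wise by H3 first (`normalize_to_h3()`) so modification
   density is not confounded by nucleosome loss or gain.
3. **Promoter architecture.** The NDR (nucleosome-depleted region) size is
   the edge-to-edge gap between the called -1 and +1 nucleosomes, floored
   at 0 (`ndr_sizes()`); medians are compared across classes with the
   Wilcoxon rank-sum test.
4. **Gene body and turnover.** Modification levels in non-overlapping 50 bp
   windows tiling each transcribed region are pooled across genes and
   correlated with the sense and antisense counts in the same windows
   (`body_window_table()`, `body_window_correlation()`). Histone-turnover
   rates arrive on microarray probe intervals; a gene region (the -1..+4
   nucleosome span, or each nucleosome singly) gets the *maximum* rate over
   all probes overlapping it by at least 1 bp (`region_turnover()`,
   `nucleosome_turnover()`).
5. **Promoter factors.** A genes-by-factors occupancy matrix is screened
   factor-by-factor with the two-sided Wilcoxon rank-sum test between two
   gene groups; a factor is *enriched* when its median is higher in the
   first group and its raw p-value is below 1e-4 (`factor_enrichment()`).
   No multiple-testing correction is applied — the procedure is a hard raw-p
   cutoff, and the false-positive behaviour that implies is part of what the
   calibration tests quantify.
6. **Mutant contrast.** NET-seq libraries from deletion strains are scaled
   to a common total (`normalize_libraries()`), mutant counts are mapped
   through the wild-type class boundaries (`reassign_classes()`), and genes
   are grouped by class shift: *increased* (up >= 2 classes), *decreased*
   (down >= 2), *unchanged* (same class). Genes moving exactly one class
   match none of those definitions; they are kept in an explicit `excluded`
   group so the grouping always partitions the gene set. Per shift group,
   mutant-minus-wild-type difference metagenes are computed with Wilcoxon
   contrasts against the unchanged group at configured positions
   (`difference_profile()`).

## Conventions that everything else depends on

* Coordinates are 0-based, half-open `[start, end)` internally; BED is
  native, GFF3 is shifted on read.
* All windows are anchored on the sense TSS and expressed in
  transcriptional orientation: relative position $r$ is genomic $tss + r$
  on a `+` gene and $tss - r$ on a `-` gene, and returned vectors always
  run 5' to 3' of the *sense* transcript. The antisense strand of a `+`
  gene is Crick; of a `-` gene, Watson.
* NET-seq tracks are per-base counts; a window count is the *sum* of
  per-base values in the half-open window. ChIP-style tracks are averaged
  per bin instead. Both statistics are exposed (`stat = "sum"` / `"mean"`).
* Missing data is `NA` and never 0: positions off a chromosome end and
  positions where H3 falls below the normalisation floor are excluded from
  both the numerator and denominator of every average.

## Rank statistics

All inference uses two self-contained rank procedures (`spearman_cor()`,
`wilcoxon_rank_sum()`), because every published number this pipeline mirrors
is a Spearman coefficient or a rank-sum p-value. Spearman is computed as
Pearson on tie-averaged ranks; constant margins yield a flagged-undefined
result rather than an error, since constant bins occur routinely in
genome-wide profiling. The Wilcoxon statistic is Mann-Whitney U; for small
samples (both sizes at most 12 by default) the two-sided p-value is exact,
computed from the conditional distribution of the rank sum given the
observed (possibly tied) ranks via a counting dynamic program equivalent to
enumerating all $\binom{n_1+n_2}{n_1}$ assignments. Larger samples use the
normal approximation with the standard tie variance correction and, by
default, a 0.5 continuity correction; the group sizes in this pipeline are
in the hundreds, so the approximate path is the operative one. Whether the
original analyses used continuity correction is not documented; both
variants are exposed. Directionality in the enrichment stage comes from a
median comparison plus the two-sided p, not from one-sided tests.

## The synthetic-data generator

No raw dataset ships with the package; instead `generate_dataset()` builds
a complete synthetic study whose statistical structure matches what the
real compendium looks like, with known ground truth. Defaults (all
overridable via `generator_config()`):

* **Genome**: 2000 genes on two chromosomes (~4.5 Mb total), lengths
  log-normal (median ~1.2 kb, clamped to 0.4-4 kb), intergenic gaps
  600-1200 bp. Small enough that the full pipeline runs in seconds.
* **Antisense counts**: zero-inflated negative binomial. With probability
  0.24 a gene draws from {0, 1}; otherwise from NB(mu = 15, k = 0.6)
  *truncated to counts >= 2*. The truncation is deliberate: an untruncated
  NB(15, 0.6) places ~22% of its mass on 0-1, which would inflate the
  bottom class to ~40% — the zero-inflation mass alone is meant to set the
  bottom-class fraction at 24%.
* **Sense counts**: log-normal (log-mean 5.5, log-sd 1.0), drawn
  independently of antisense, matching the near-zero sense/antisense rank
  correlation the classification stage should report.
* **Promoter geometry**: the +1 nucleosome starts at the TSS; the -1
  nucleosome ends `w` bp upstream, where `w = 110 - 15 * (class - 1)` bp
  (jitter sd 4 bp) — NDR narrowing is planted as a monotone function of
  antisense class. Nucleosomes are 147 bp at a 165 bp period through +4;
  occupancy is a sum of Gaussian bumps (sd 35 bp) over each nucleosome
  midpoint plus phased filler bumps continuing the array upstream of -1 and
  downstream of +4, so intergenic DNA is occupied and the profile minimum
  near the TSS genuinely sits in the NDR.
* **Marks**: the acetylation proxy multiplies H3 by
  `0.3 + 0.25 * log(1 + antisense)` over the gene (promoter included); the
  K36me3 proxy multiplies H3 by a 5'→3' body ramp times
  `max(0, 0.5 + 0.15 * log(1 + sense) - 0.2 * log(1 + antisense))`.
  Effects enter through `log(1 + count)` because the planted associations
  are meant to be monotone, not linear, and tracks must stay positive.
  Multiplicative log-normal noise (sd 0.1) is applied per base.
* **Turnover**: probes tile the genome at 250 bp; a probe overlapping a
  gene's -1..+4 span gets rate `1.0 + 0.3 * log(1 + antisense)` plus
  Gaussian noise (sd 0.1).
* **Factors**: a 2000 x 202 standard-normal occupancy matrix with 5 planted
  columns shifted by `0.5 * standardised log(1 + antisense)`.
* **Mutant**: 10% of genes get antisense x5 and another 10% x0.1; sense
  counts receive small independent log-normal noise. Up-planted genes are
  drawn from wild-type classes 2-3 and down-planted from classes 4-5 — a
  multiplicative fold cannot move a 0-read gene or a top-class gene by two
  classes, so eligibility is part of the planted design, and recovery below
  100% near class boundaries is expected and correct. All tracks are
  regenerated from the perturbed counts through the same response
  functions.

What the generator does **not** emulate: mappability and sequencing error,
replication timing, transcript isoforms, CUT/SUT annotation, correlated
factor occupancies, or any coupling between sense and antisense
transcription. Passing recovery tests therefore demonstrates that the
pipeline's statistics and conventions are implemented correctly — not that
the biological associations would be detectable at the same strength in
real data, where effect sizes are far smaller and confounded.

## Numerical and design choices

* "Considerable" gene overlap has no canonical cutoff; `filter_genes()`
  defaults to removing *any* overlapping pair (limit 0 bp), the strictest
  reading, with the limit exposed and echoed to the run log.
* The extremum tests search the pooled mean profile of the two compared
  groups within ±300 bp of the TSS by default (the scale of the
  classification window); locating the extremum on the first group's own
  profile is available via `extremum_on = "group_a"`.
* NDR sizes are edge-to-edge (0 for abutting or overlapping calls), which
  matches the intuition of a depleted *region*; dyad-to-dyad distances
  (`mode = "dyad"`, roughly one nucleosome width larger) are available
  because published median NDR figures do not always state the convention.
* The 50 bp gene-body "sliding" window is tiled non-overlapping
  (step = width) by default, with the step exposed; correlations are pooled
  across all gene-windows into a single coefficient rather than averaged
  per gene.
* Turnover per probe requires >= 1 bp overlap under half-open intervals: a
  probe that merely touches a region boundary contributes nothing.
* Degenerate inputs have defined behaviour rather than errors where a
  genome-wide run must survive them: constant correlation margins are
  flagged undefined; genes missing a -1 or +1 call are skipped with a
  logged reason; factors with under two observations per group are excluded
  with a log entry; fully tied rank-sum samples give p = 1.
* `run_pipeline()` output is fully determined by (inputs, config, seed);
  every applied default is written to `run_log.txt`.

## Reference problem sizes

The test-suite and acceptance checks run the generator at its default 2000
genes (two ~2 Mb chromosomes), 10,000 null simulations for type-I
calibration of the rank-sum test, 1,000 random instances for the Spearman
oracle, and 10 generator seeds for the enrichment error-control check.
These sizes were chosen so each planted effect is detected with large
margin while a full check pass stays in the minutes range on one core.

## A short tour

```{r tour, eval = FALSE}
cfg <- generator_config(seed = 1)
ds <- generate_dataset(cfg)

genes <- filter_genes(ds$genes)
anti <- count_window_reads(genes, ds$netseq, "antisense")
classes <- assign_five_classes(anti)
glance(classes)

grp <- split(classes$gene_id, classes$class)
autoplot(metagene_profile(genes, ds$occupancy, group = grp))

counts <- dplyr::tibble(gene_id = genes$gene_id,
                        sense = count_window_reads(genes, ds$netseq, "sense")$count,
                        antisense = anti$count)
autoplot(correlation_profile(genes, normalize_to_h3(ds$mod_h3ac, ds$h3), counts))

ndr <- ndr_sizes(ds$nucleosomes, genes)
group_median_ndr(ndr, dplyr::tibble(gene_id = classes$gene_id,
                                    group = as.character(classes$class)),
                 contrast = c("5", "1"))
```

## Known limitations

* Tracks are dense per-base vectors; at yeast scale this is a few hundred
  MB at most, but the container is not suited to mammalian genomes without
  a binned resolution.
* Only BED6/GFF3/bedGraph/TSV are parsed; BAM/FASTQ and bigWig are out of
  scope (counts are consumed at the summary level).
* The five-class machinery assumes enough distinct counts above 1 to form
  four upper classes and reports the achievable number when the input
  cannot support five.
* The mutant module reports descriptive contrasts only; nothing in it
  supports causal claims about the deleted factors.
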