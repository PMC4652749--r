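# antisensr

Genome-wide association of nascent **antisense transcription** with
**chromatin architecture** in budding yeast, as a tidyverse-style R package.

Most yeast genes are transcribed on both strands, but antisense transcripts
are degraded so quickly that only nascent-transcription assays (NET-seq)
reveal how common antisense activity is. `antisensr` is for genomicists who
have strand-specific nascent-transcription tracks plus standard chromatin
tracks (nucleosome occupancy, H3 and its modifications, factor ChIP,
histone-turnover probes) and want to ask, gene by gene: *what does chromatin
look like at genes with a lot of antisense transcription versus almost
none — and is that signature different from the one left by sense
transcription?*

## What it computes

Genes are ranked by antisense NET-seq reads $A_g$ in the 300 bp window
$[0, 300)$ downstream of the sense TSS and split into five classes: class 1
is exactly the genes with $A_g \le 1$; the rest are rank-split into four
near-equal classes. Around that classification the package provides

* TSS-anchored **metagene profiles** per class, and per-position **Spearman
  correlation profiles** $r_s(\text{signal}_p, A_g)$ and
  $r_s(\text{signal}_p, S_g)$ for sense counts $S_g$, with histone marks
  normalised position-wise to H3;
* **NDR sizes** — the edge-to-edge gap between the called −1 and +1
  nucleosomes — summarised per class with Wilcoxon rank-sum contrasts;
* **gene-body correlations** of modification levels with sense/antisense
  counts in matched 50 bp windows, and **histone-turnover** assignment as
  the max rate over probes overlapping each −1..+4 nucleosome;
* **promoter-factor enrichment**: per-factor two-sided Wilcoxon rank-sum
  between two gene groups, enriched = higher median in group A and raw
  $p < 10^{-4}$ (no multiple-testing correction, by design);
* **mutant class shifts**: libraries normalised to equal totals, mutant
  counts mapped through wild-type class boundaries, genes grouped as
  increased / decreased / unchanged (±2-class rule), with
  mutant-minus-wild-type difference metagenes;
* a seeded **synthetic-data generator** that plants all of the above
  (zero-inflated NB antisense counts, independent log-normal sense counts,
  class-dependent NDR narrowing, log-linear acetylation/K36me3/turnover
  responses, 5 planted factors of 202) so every stage is testable against
  ground truth.

All user-facing functions take a data frame first and return tibbles;
result objects have `tidy()`/`glance()` and `autoplot()` methods.

## Worked example

```r
library(antisensr)

cfg <- generator_config(seed = 1)      # 2000 genes, two ~2 Mb chromosomes
ds  <- generate_dataset(cfg)

genes   <- filter_genes(ds$genes)      # drop dubious/overlapping genes
anti    <- count_window_reads(genes, ds$netseq, "antisense")
classes <- assign_five_classes(anti)
glance(classes)
#> # A tibble: 1 × 10
#>   n_genes n_class1 n_class2 n_class3 n_class4 n_class5 min_count_class2 ...
#> 1    2000      479      430      349      368      374                2

counts <- dplyr::tibble(
  gene_id = genes$gene_id,
  sense = count_window_reads(genes, ds$netseq, "sense")$count,
  antisense = anti$count)
spearman_cor(counts$sense, counts$antisense)
#> # A tibble: 1 × 3
#>       rho     n defined
#> 1 -0.0223  2000 TRUE

ndr <- ndr_sizes(ds$nucleosomes, genes)
grp <- dplyr::tibble(gene_id = classes$gene_id,
                     group = as.character(classes$class))
group_median_ndr(ndr, grp, contrast = c("5", "1"))
#> # A tibble: 5 × 3
#>   group     n median_ndr
#> 1 1       479        110
#> 2 2       430         95
#> 3 3       349         80
#> 4 4       368         65
#> 5 5       374         50
```

Class 1 holds 479/2000 genes (24%, the 0-or-1-read class); sense and
antisense counts are essentially uncorrelated (r_s = −0.02); and the median
NDR narrows monotonically from 110 bp (lowest antisense class) to 50 bp
(highest), the top-vs-bottom Wilcoxon contrast being overwhelming
(p ≈ 4e−139 on this planted simulation). `autoplot()` on
`metagene_profile()` / `correlation_profile()` / `factor_enrichment()`
results draws the corresponding figures, and `run_pipeline()` executes all
stages from one YAML/list config into a TSV report directory.

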