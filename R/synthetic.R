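#' Configuration for the synthetic-dataset generator
#'
#' Defaults emulate the statistical structure of the published yeast
#' NET-seq/chromatin compendium the pipeline was designed around: ~24% of
#' genes with 0-1 antisense reads in the 300 bp window, antisense counts
#' otherwise negative-binomial (mu 15, dispersion 0.6, truncated to >= 2 so
#' the zero-inflation mass alone fixes the bottom-class fraction), sense
#' counts log-normal and independent of antisense, NDR base width 110 bp
#' narrowing 15 bp per antisense class step, nucleosomes 147 bp at 165 bp
#' period with Gaussian occupancy bumps (sd 35 bp), an acetylation proxy
#' increasing and a K36me3 proxy decreasing in log(1 + antisense),
#' turnover-probe rates increasing in log(1 + antisense), 250 bp probe
#' tiling, and a 202-factor promoter occupancy matrix with 5 planted
#' factors at 0.5 sd effect. The mutant counterpart scales antisense counts
#' 5-fold up in 10% of genes and 10-fold down in another 10%.
#'
#' @param seed integer RNG seed.
#' @param ... overrides for any default listed above (see source for the
#'   full field list).
#' @return a validated `generator_config` list.
#' @export
generator_config <- function(seed = 1L, ...) {
  cfg <- list(
    seed = as.integer(seed),
    n_genes = 2000L, n_chroms = 2L, margin = 3000L,
    gene_len_meanlog = 7.1, gene_len_sdlog = 0.4,
    gene_len_min = 400L, gene_len_max = 4000L,
    intergenic_min = 600L, intergenic_max = 1200L,
    zero_inflation = 0.24, as_mu = 15, as_size = 0.6,
    sense_meanlog = 5.5, sense_sdlog = 1.0,
    ndr_base = 110, ndr_step = 15, ndr_jitter_sd = 4,
    nuc_width = 147L, nuc_period = 165L, bump_sd = 35, occ_baseline = 0.15,
    acet_intercept = 0.3, acet_slope = 0.25,
    k36_intercept = 0.5, k36_sense_slope = 0.15, k36_antisense_slope = -0.2,
    turnover_base = 1.0, turnover_slope = 0.3, turnover_noise_sd = 0.1,
    probe_width = 250L,
    noise_sd = 0.1,
    n_factors = 202L, n_planted = 5L, planted_effect = 0.5,
    mut_frac_up = 0.1, mut_frac_down = 0.1,
    mut_fold_up = 5, mut_fold_down = 0.1, mut_sense_noise_sd = 0.05
  )
  dots <- list(...)
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown))
    abort(paste0("unknown config field(s): ", paste(unknown, collapse = ", ")))
  cfg[names(dots)] <- dots
  validate_generator_config(cfg)
  structure(cfg, class = "generator_config")
}

validate_generator_config <- function(cfg) {
  bad <- character(0)
  pos <- c("n_genes", "n_chroms", "margin", "gene_len_min", "gene_len_max",
           "intergenic_min", "as_mu", "as_size", "ndr_base", "ndr_step",
           "nuc_width", "nuc_period", "bump_sd", "probe_width", "noise_sd",
           "turnover_noise_sd", "n_factors")
  for (f in pos) if (!is.numeric(cfg[[f]]) || cfg[[f]] <= 0)
    bad <- c(bad, paste0(f, " must be positive"))
  if (cfg$zero_inflation < 0 || cfg$zero_inflation > 1)
    bad <- c(bad, "zero_inflation must lie in [0, 1]")
  if (cfg$mut_frac_up < 0 || cfg$mut_frac_down < 0 ||
      cfg$mut_frac_up + cfg$mut_frac_down > 1)
    bad <- c(bad, "mutant fractions must be non-negative and sum to <= 1")
  if (cfg$n_planted > cfg$n_factors)
    bad <- c(bad, "n_planted must not exceed n_factors")
  if (length(bad)) abort(paste0("invalid config: ", paste(bad, collapse = "; ")))
  invisible(cfg)
}

#' Component samplers of the synthetic generator
#'
#' Exposed so calibration studies (e.g. repeated enrichment runs) can draw
#' just the pieces they need. All sampling happens in the caller's RNG
#' state; seed outside.
#'
#' @param cfg a [generator_config()].
#' @name synthetic_samplers
NULL

#' @rdname synthetic_samplers
#' @export
sample_antisense_counts <- function(cfg) {
  n <- cfg$n_genes
  inflated <- runif(n) < cfg$zero_inflation
  counts <- integer(n)
  counts[inflated] <- rbinom(sum(inflated), 1L, 0.5)
  k <- sum(!inflated)
  if (k) {
    draws <- integer(0)
    while (length(draws) < k) {
      cand <- rnbinom(2L * (k - length(draws)) + 10L,
                      mu = cfg$as_mu, size = cfg$as_size)
      draws <- c(draws, cand[cand >= 2L])
    }
    counts[!inflated] <- draws[seq_len(k)]
  }
  counts
}

#' @rdname synthetic_samplers
#' @export
sample_sense_counts <- function(cfg) {
  pmax(0L, as.integer(round(rlnorm(cfg$n_genes, cfg$sense_meanlog,
                                   cfg$sense_sdlog))))
}

#' @rdname synthetic_samplers
#' @param antisense integer antisense counts (length `n_genes`); planted
#'   factor effects scale with standardised `log(1 + antisense)`.
#' @export
sample_occupancy_matrix <- function(cfg, antisense) {
  n <- cfg$n_genes
  stopifnot(length(antisense) == n)
  m <- matrix(rnorm(n * cfg$n_factors), nrow = n)
  colnames(m) <- sprintf("factor_%03d", seq_len(cfg$n_factors))
  planted <- sort(sample.int(cfg$n_factors, cfg$n_planted))
  z <- as.numeric(scale(log1p(antisense)))
  for (j in planted) m[, j] <- m[, j] + cfg$planted_effect * z
  list(matrix = m, planted = colnames(m)[planted])
}

# Lay out non-overlapping genes along n_chroms chromosomes.
layout_genes <- function(cfg) {
  n <- cfg$n_genes
  len <- pmin(cfg$gene_len_max,
              pmax(cfg$gene_len_min,
                   round(rlnorm(n, cfg$gene_len_meanlog, cfg$gene_len_sdlog))))
  gap <- round(runif(n, cfg$intergenic_min, cfg$intergenic_max))
  strand <- sample(c("+", "-"), n, replace = TRUE)
  per_chrom <- rep(seq_len(cfg$n_chroms),
                   each = ceiling(n / cfg$n_chroms))[seq_len(n)]
  start <- integer(n)
  chrom_sizes <- integer(cfg$n_chroms)
  for (ch in seq_len(cfg$n_chroms)) {
    i <- which(per_chrom == ch)
    pos <- cfg$margin
    for (k in i) {
      start[k] <- pos
      pos <- pos + len[k] + gap[k]
    }
    chrom_sizes[ch] <- pos + cfg$margin
  }
  chroms <- sprintf("chr%s", utils::as.roman(seq_len(cfg$n_chroms)))
  g <- tibble(
    gene_id = sprintf("g%04d", seq_len(n)),
    chrom = chroms[per_chrom], start = start, end = start + len,
    strand = strand, dubious = FALSE) |>
    mutate(tss = ifelse(strand == "+", .data$start, .data$end - 1L),
           tes = ifelse(strand == "+", .data$end - 1L, .data$start))
  list(genes = g, chrom_sizes = setNames(chrom_sizes, chroms))
}

# Nucleosome calls -1..+4 around each TSS given per-gene NDR widths.
place_nucleosomes <- function(genes, ndr_width, cfg) {
  offs <- lapply(seq_len(nrow(genes)), function(i) {
    w <- ndr_width[i]
    a <- c(-w - cfg$nuc_width, (0:3) * cfg$nuc_period)       # oriented starts
    b <- a + cfg$nuc_width
    if (genes$strand[i] == "+") {
      cbind(genes$tss[i] + a, genes$tss[i] + b)
    } else {
      cbind(genes$tss[i] - b + 1L, genes$tss[i] - a + 1L)
    }
  })
  m <- do.call(rbind, offs)
  nucleosome_map(
    gene_id = rep(genes$gene_id, each = 5L),
    index = rep(c(-1L, 1L, 2L, 3L, 4L), nrow(genes)),
    chrom = rep(genes$chrom, each = 5L),
    start = as.integer(m[, 1L]), end = as.integer(m[, 2L]))
}

# Scatter `count` reads uniformly over relative window [from, to) of a gene,
# returning increments to apply to the target strand vector.
scatter_reads <- function(count, width) {
  if (count <= 0L) return(NULL)
  tabulate(sample.int(width, count, replace = TRUE), width)
}

oriented_index <- function(tss, strand, width) {
  if (strand == "+") (tss):(tss + width - 1L) + 1L
  else (tss):(tss - width + 1L) + 1L
}

build_netseq <- function(genes, antisense, sense, chrom_sizes) {
  watson <- vector("list", length(chrom_sizes))
  crick <- vector("list", length(chrom_sizes))
  names(watson) <- names(crick) <- names(chrom_sizes)
  for (ch in names(chrom_sizes)) {
    w <- numeric(chrom_sizes[[ch]])
    cr <- numeric(chrom_sizes[[ch]])
    for (i in which(genes$chrom == ch)) {
      st <- genes$strand[i]; tss <- genes$tss[i]
      len <- genes$end[i] - genes$start[i]
      a_inc <- scatter_reads(antisense[i], 300L)
      s_inc <- scatter_reads(sense[i], len)
      if (!is.null(a_inc)) {
        idx <- oriented_index(tss, st, 300L)
        if (st == "-") w[idx] <- w[idx] + a_inc else cr[idx] <- cr[idx] + a_inc
      }
      if (!is.null(s_inc)) {
        idx <- oriented_index(tss, st, len)
        if (st == "+") w[idx] <- w[idx] + s_inc else cr[idx] <- cr[idx] + s_inc
      }
    }
    watson[[ch]] <- w
    crick[[ch]] <- cr
  }
  stranded_track(watson, crick)
}

build_chromatin <- function(genes, nucmap, antisense, sense, cfg, chrom_sizes) {
  half <- ceiling(3 * cfg$bump_sd)
  kernel <- exp(-((-half:half)^2) / (2 * cfg$bump_sd^2))
  core <- lapply(chrom_sizes, function(sz) rep(cfg$occ_baseline, sz))
  # called nucleosomes, plus filler arrays continuing the 165 bp phasing
  # upstream of -1 and downstream of +4 so intergenic DNA and long gene
  # bodies are occupied too (fillers carry no call record)
  mid <- (nucmap$start + nucmap$end) %/% 2L
  fill <- purrr::map(split(seq_len(nrow(nucmap)), nucmap$gene_id), function(i) {
    lo <- min(mid[i]); hi <- max(mid[i])
    c(lo - cfg$nuc_period * (1:3), hi + cfg$nuc_period * (1:3))
  })
  all_mid <- c(mid, unlist(fill, use.names = FALSE))
  all_chrom <- c(nucmap$chrom,
                 rep(nucmap$chrom[match(names(fill), nucmap$gene_id)],
                     lengths(fill)))
  for (i in seq_along(all_mid)) {
    ch <- all_chrom[i]
    idx <- (all_mid[i] - half):(all_mid[i] + half) + 1L
    ok <- idx >= 1L & idx <= length(core[[ch]])
    core[[ch]][idx[ok]] <- core[[ch]][idx[ok]] + kernel[ok]
  }
  acet_factor <- lapply(chrom_sizes, function(sz) rep(cfg$acet_intercept, sz))
  k36_gain <- lapply(chrom_sizes, numeric)   # ramp * response, 0 outside genes
  for (i in seq_len(nrow(genes))) {
    ch <- genes$chrom[i]
    la <- log1p(antisense[i]); ls <- log1p(sense[i])
    if (genes$strand[i] == "+") {
      span <- (genes$start[i] - 300L):(genes$end[i] - 1L) + 1L
      body <- (genes$tss[i]):(genes$tes[i]) + 1L
      ramp <- seq(0, 1, length.out = length(body))
    } else {
      span <- (genes$start[i]):(genes$end[i] + 299L) + 1L
      body <- (genes$tes[i]):(genes$tss[i]) + 1L
      ramp <- seq(1, 0, length.out = length(body))
    }
    span <- span[span >= 1L & span <= length(acet_factor[[ch]])]
    acet_factor[[ch]][span] <- cfg$acet_intercept + cfg$acet_slope * la
    g <- max(0, cfg$k36_intercept + cfg$k36_sense_slope * ls +
               cfg$k36_antisense_slope * la)
    ok <- body >= 1L & body <= length(k36_gain[[ch]])
    k36_gain[[ch]][body[ok]] <- g * ramp[ok]
  }
  noisy <- function(base, f) {
    lapply(setNames(names(base), names(base)), function(ch) {
      f(base[[ch]], rnorm(length(base[[ch]]), 0, cfg$noise_sd))
    })
  }
  occupancy <- noisy(core, function(v, e) pmax(0, v + e))
  h3 <- noisy(core, function(v, e) pmax(0.05, v + e))
  acet <- lapply(setNames(names(core), names(core)), function(ch) {
    h3[[ch]] * acet_factor[[ch]] * exp(rnorm(length(h3[[ch]]), 0, cfg$noise_sd))
  })
  k36 <- lapply(setNames(names(core), names(core)), function(ch) {
    h3[[ch]] * k36_gain[[ch]] * exp(rnorm(length(h3[[ch]]), 0, cfg$noise_sd))
  })
  list(occupancy = unstranded_track(occupancy), h3 = unstranded_track(h3),
       mod_h3ac = unstranded_track(acet), mod_h3k36me3 = unstranded_track(k36))
}

build_probes <- function(nucmap, antisense, genes, cfg, chrom_sizes) {
  probes <- purrr::imap(as.list(chrom_sizes), function(sz, ch) {
    starts <- seq(0L, sz - cfg$probe_width, by = cfg$probe_width)
    tibble(chrom = ch, start = starts, end = starts + cfg$probe_width)
  }) |> bind_rows()
  span <- nucmap |> group_by(.data$gene_id) |>
    summarise(chrom = .data$chrom[1L], start = min(.data$start),
              end = max(.data$end), .groups = "drop")
  la <- log1p(antisense)[match(span$gene_id, genes$gene_id)]
  q <- GenomicRanges::GRanges(probes$chrom,
                              IRanges::IRanges(probes$start + 1L, probes$end))
  s <- GenomicRanges::GRanges(span$chrom,
                              IRanges::IRanges(span$start + 1L, span$end))
  hits <- GenomicRanges::findOverlaps(q, s)
  effect <- numeric(nrow(probes))
  if (length(hits)) {
    agg <- tapply(cfg$turnover_slope * la[S4Vectors::subjectHits(hits)],
                  S4Vectors::queryHits(hits), max)
    effect[as.integer(names(agg))] <- as.numeric(agg)
  }
  probes$rate <- cfg$turnover_base + effect +
    rnorm(nrow(probes), 0, cfg$turnover_noise_sd)
  probes
}

#' Generate a complete seeded synthetic dataset
#'
#' Produces, in memory, every input the pipeline consumes -- gene
#' annotations, stranded per-base NET-seq counts, nucleosome calls and
#' occupancy, H3 and modification-proxy tracks, turnover probes, a promoter
#' factor-occupancy matrix -- together with the ground truth needed to
#' verify recovery (true counts, NDR widths, planted factors). Identical
#' config (including seed) gives identical output.
#'
#' @param cfg a [generator_config()].
#' @return a `synthetic_dataset` list; see the vignette for the layout.
#' @export
generate_dataset <- function(cfg) {
  validate_generator_config(cfg)
  set.seed(cfg$seed)
  lay <- layout_genes(cfg)
  genes <- lay$genes
  antisense <- sample_antisense_counts(cfg)
  sense <- sample_sense_counts(cfg)
  cnt <- tibble(gene_id = genes$gene_id, count = antisense)
  classes <- if (all(antisense <= 1L)) {
    # degenerate (e.g. zero_inflation = 1): only the bottom class exists
    new_class_assignment(cnt |> mutate(class = 1L),
                         setNames(rep(NA_real_, 4L), paste0("class", 2:5)))
  } else {
    assign_five_classes(cnt)
  }
  ndr_width <- pmax(20, round(cfg$ndr_base -
                                cfg$ndr_step * (classes$class - 1L) +
                                rnorm(cfg$n_genes, 0, cfg$ndr_jitter_sd)))
  nucmap <- place_nucleosomes(genes, ndr_width, cfg)
  netseq <- build_netseq(genes, antisense, sense, lay$chrom_sizes)
  chrom <- build_chromatin(genes, nucmap, antisense, sense, cfg,
                           lay$chrom_sizes)
  probes <- build_probes(nucmap, antisense, genes, cfg, lay$chrom_sizes)
  occ <- sample_occupancy_matrix(cfg, antisense)
  structure(list(
    config = cfg, chrom_sizes = lay$chrom_sizes, genes = genes,
    counts = tibble(gene_id = genes$gene_id, sense = sense,
                    antisense = antisense),
    classes = classes, ndr_width = ndr_width, nucleosomes = nucmap,
    netseq = netseq, occupancy = chrom$occupancy, h3 = chrom$h3,
    mod_h3ac = chrom$mod_h3ac, mod_h3k36me3 = chrom$mod_h3k36me3,
    probes = probes,
    occupancy_matrix = bind_cols(tibble(gene_id = genes$gene_id),
                                 as_tibble(occ$matrix)),
    ground_truth = list(
      seed = cfg$seed, antisense = antisense, sense = sense,
      class = classes$class, ndr_width = ndr_width,
      planted_factors = occ$planted)
  ), class = "synthetic_dataset")
}

#' @export
print.synthetic_dataset <- function(x, ...) {
  cat(sprintf(
    "<synthetic_dataset: %d genes on %d chromosome(s) (%s bp), seed %d%s>\n",
    nrow(x$genes), length(x$chrom_sizes),
    format(sum(x$chrom_sizes), big.mark = ","), x$config$seed,
    if (!is.null(x$perturbation)) ", mutant" else ""))
  invisible(x)
}

#' Generate the mutant counterpart of a wild-type dataset
#'
#' Scales the antisense counts of planted gene sets by the configured folds
#' (up-planted genes are drawn from wild-type classes 2-3 and down-planted
#' from classes 4-5, since a multiplicative fold cannot move a 0-read or
#' top-class gene by two classes), perturbs sense counts with small
#' independent noise, and regenerates NET-seq and chromatin tracks from the
#' perturbed counts through the same planted response functions (NDR widths
#' follow the gene's class on the wild-type scale). The perturbation labels
#' are returned in `$perturbation`.
#'
#' @param cfg the [generator_config()] used for the wild-type.
#' @param wt a wild-type [generate_dataset()] result.
#' @return a `synthetic_dataset` with an extra `perturbation` tibble.
#' @export
generate_mutant <- function(cfg, wt) {
  validate_generator_config(cfg)
  set.seed(cfg$seed + 1000003L)
  n <- cfg$n_genes
  wt_class <- wt$classes$class
  elig_up <- which(wt_class %in% c(2L, 3L))
  elig_down <- which(wt_class %in% c(4L, 5L))
  n_up <- min(length(elig_up), round(cfg$mut_frac_up * n))
  n_down <- min(length(elig_down), round(cfg$mut_frac_down * n))
  up <- sort(sample(elig_up, n_up))
  down <- sort(sample(elig_down, n_down))
  antisense <- wt$counts$antisense
  antisense[up] <- as.integer(round(antisense[up] * cfg$mut_fold_up))
  antisense[down] <- as.integer(round(antisense[down] * cfg$mut_fold_down))
  sense <- pmax(0L, as.integer(round(
    wt$counts$sense * exp(rnorm(n, 0, cfg$mut_sense_noise_sd)))))
  mut_classes <- reassign_classes(tibble(gene_id = wt$genes$gene_id,
                                         count = antisense), wt$classes)
  ndr_width <- pmax(20, round(cfg$ndr_base -
                                cfg$ndr_step * (mut_classes$class - 1L) +
                                rnorm(n, 0, cfg$ndr_jitter_sd)))
  nucmap <- place_nucleosomes(wt$genes, ndr_width, cfg)
  netseq <- build_netseq(wt$genes, antisense, sense, wt$chrom_sizes)
  chrom <- build_chromatin(wt$genes, nucmap, antisense, sense, cfg,
                           wt$chrom_sizes)
  label <- rep("none", n)
  label[up] <- "up"; label[down] <- "down"
  structure(list(
    config = cfg, chrom_sizes = wt$chrom_sizes, genes = wt$genes,
    counts = tibble(gene_id = wt$genes$gene_id, sense = sense,
                    antisense = antisense),
    classes = mut_classes, ndr_width = ndr_width, nucleosomes = nucmap,
    netseq = netseq, occupancy = chrom$occupancy, h3 = chrom$h3,
    mod_h3ac = chrom$mod_h3ac, mod_h3k36me3 = chrom$mod_h3k36me3,
    perturbation = tibble(gene_id = wt$genes$gene_id, label = label),
    ground_truth = list(antisense = antisense, sense = sense,
                        planted_up = wt$genes$gene_id[up],
                        planted_down = wt$genes$gene_id[down])
  ), class = "synthetic_dataset")
}

#' Write a synthetic dataset to standard-format files
#'
#' Writes `genes.bed`, `netseq_{watson,crick}.bedGraph`,
#' `occupancy.bedGraph`, `h3.bedGraph`, `mod_h3ac.bedGraph`,
#' `mod_h3k36me3.bedGraph`, `nucleosome_calls.bed`, `turnover_probes.tsv`,
#' `occupancy_matrix.tsv` (wild-type only) and `ground_truth.json` into
#' `dir`. Byte-identical for identical datasets.
#'
#' @param ds a [generate_dataset()] / [generate_mutant()] result.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(ds, dir) {
  if (!dir.exists(dir) && !dir.create(dir, recursive = TRUE))
    abort(paste0("cannot create output directory: ", dir))
  p <- function(f) file.path(dir, f)
  write_genes_bed(ds$genes, p("genes.bed"))
  write_track(ds$netseq, p("netseq"))
  for (nm in c("occupancy", "h3", "mod_h3ac", "mod_h3k36me3"))
    write_track(ds[[nm]], p(nm))
  write_nucleosome_calls(ds$nucleosomes, p("nucleosome_calls.bed"))
  if (!is.null(ds$probes)) readr::write_tsv(ds$probes, p("turnover_probes.tsv"))
  if (!is.null(ds$occupancy_matrix))
    readr::write_tsv(ds$occupancy_matrix, p("occupancy_matrix.tsv"))
  jsonlite::write_json(ds$ground_truth, p("ground_truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
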