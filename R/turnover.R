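#' Gene-body 50 bp window table
#'
#' Tiles each gene's transcribed region `[TSS, TES]` with non-overlapping
#' windows of `width` bp in transcriptional orientation (a partial terminal
#' window is dropped) and records, per window, the mean modification signal
#' and the sense and antisense nascent read counts in the same interval.
#' `step` defaults to `width` (abutting tiles); smaller steps give
#' overlapping sliding windows.
#'
#' @param genes gene tibble.
#' @param mod_track unstranded modification track (H3-normalise first if
#'   appropriate).
#' @param netseq stranded NET-seq track.
#' @param width,step window width and step in bp.
#' @return tibble: `gene_id`, `window`, `rel_start`, `mod`, `sense`,
#'   `antisense`.
#' @export
body_window_table <- function(genes, mod_track, netseq, width = 50L,
                              step = width) {
  rows <- purrr::map(seq_len(nrow(genes)), function(i) {
    len <- abs(genes$tes[i] - genes$tss[i]) + 1L
    if (len < width) return(NULL)
    starts <- seq(0L, len - width, by = step)
    mod <- window_values_at(mod_track, genes$chrom[i], genes$tss[i],
                            genes$strand[i], 0L, max(starts) + width,
                            "unstranded")
    sen <- window_values_at(netseq, genes$chrom[i], genes$tss[i],
                            genes$strand[i], 0L, max(starts) + width, "sense")
    anti <- window_values_at(netseq, genes$chrom[i], genes$tss[i],
                             genes$strand[i], 0L, max(starts) + width,
                             "antisense")
    win_stat <- function(v, f) vapply(starts, function(s) {
      x <- v[(s + 1L):(s + width)]
      if (all(is.na(x))) NA_real_ else f(x, na.rm = TRUE)
    }, numeric(1))
    tibble(gene_id = genes$gene_id[i], window = seq_along(starts),
           rel_start = starts, mod = win_stat(mod, mean),
           sense = win_stat(sen, sum), antisense = win_stat(anti, sum))
  })
  bind_rows(rows)
}

#' Pooled gene-body correlation of a modification with transcription
#'
#' One Spearman coefficient over all gene-windows for each strand: the
#' window's modification level against its nascent sense count, and
#' separately against its antisense count.
#'
#' @param windows output of [body_window_table()].
#' @return tibble: `target` (sense/antisense), `rho`, `n`, `defined`.
#' @export
body_window_correlation <- function(windows) {
  ok <- !is.na(windows$mod)
  run <- function(target) {
    s <- spearman_cor(windows$mod[ok], windows[[target]][ok])
    tibble(target = target, rho = s$rho, n = s$n, defined = s$defined)
  }
  bind_rows(run("sense"), run("antisense"))
}

# Max probe rate over arbitrary intervals (>= 1 bp half-open overlap).
max_rate_over <- function(probes, chrom, start, end) {
  pr <- probes |> filter(!is.na(.data$rate))
  if (!nrow(pr)) {
    return(tibble(rate = rep(NA_real_, length(start)),
                  n_probes = rep(0L, length(start))))
  }
  q <- GenomicRanges::GRanges(chrom, IRanges::IRanges(start + 1L, end))
  s <- GenomicRanges::GRanges(pr$chrom, IRanges::IRanges(pr$start + 1L, pr$end))
  hits <- GenomicRanges::findOverlaps(q, s)
  rate <- rep(NA_real_, length(start))
  n_probes <- rep(0L, length(start))
  if (length(hits)) {
    qh <- S4Vectors::queryHits(hits)
    agg <- tapply(pr$rate[S4Vectors::subjectHits(hits)], qh, max)
    i <- as.integer(names(agg))
    rate[i] <- as.numeric(agg)
    tab <- table(qh)
    n_probes[as.integer(names(tab))] <- as.integer(tab)
  }
  tibble(rate = rate, n_probes = n_probes)
}

#' Histone turnover of the -1..+4 promoter-proximal region
#'
#' The region is the genomic span of a gene's called -1..+4 nucleosomes
#' (any subset present) and its turnover rate is the maximum rate over all
#' probes overlapping the region by at least 1 bp (half-open intervals; a
#' probe merely touching the boundary does not qualify). Genes with no
#' overlapping probe get `NA` and are listed in `attr(, "no_probe")`.
#'
#' @param probes probe tibble (see [read_turnover_probes()]).
#' @param map a [nucleosome_map].
#' @param genes gene tibble.
#' @return tibble: `gene_id`, `region_start`, `region_end`, `rate`,
#'   `n_probes`.
#' @export
region_turnover <- function(probes, map, genes) {
  span <- map |> filter(.data$index >= -1L, .data$index <= 4L) |>
    group_by(.data$gene_id) |>
    summarise(chrom = .data$chrom[1L], region_start = min(.data$start),
              region_end = max(.data$end), .groups = "drop") |>
    inner_join(tibble(gene_id = genes$gene_id), by = "gene_id")
  res <- max_rate_over(probes, span$chrom, span$region_start, span$region_end)
  out <- span |> mutate(rate = res$rate, n_probes = res$n_probes) |>
    select("gene_id", "region_start", "region_end", "rate", "n_probes")
  attr(out, "no_probe") <- out$gene_id[out$n_probes == 0L]
  out
}

#' Turnover per indexed nucleosome
#'
#' Like [region_turnover()] but resolved per nucleosome position -1..+4:
#' each call's rate is the max over probes overlapping that single
#' nucleosome interval.
#'
#' @inheritParams region_turnover
#' @return tibble: `gene_id`, `index`, `rate`, `n_probes`.
#' @export
nucleosome_turnover <- function(probes, map, genes) {
  sub <- map |> filter(.data$index >= -1L, .data$index <= 4L,
                       .data$gene_id %in% genes$gene_id)
  res <- max_rate_over(probes, sub$chrom, sub$start, sub$end)
  tibble(gene_id = sub$gene_id, index = sub$index,
         rate = res$rate, n_probes = res$n_probes)
}

#' Turnover-rate distributions across transcription classes
#'
#' Per nucleosome position (-1..+4) and class: quartiles of the turnover
#' rate, plus a two-sided Wilcoxon rank-sum contrast between the top and
#' bottom populated classes at every position.
#'
#' @param nuc_rates output of [nucleosome_turnover()].
#' @param classes a [class_assignment] (or tibble `gene_id`, `class`).
#' @return a `turnover_distributions` list: `$summary` (tibble `index`,
#'   `class`, `n`, `q1`, `median`, `q3`) and `$tests` (tibble `index`,
#'   `class_high`, `class_low`, `statistic`, `p_value`).
#' @export
turnover_class_distributions <- function(nuc_rates, classes) {
  d <- nuc_rates |> filter(!is.na(.data$rate)) |>
    inner_join(as_tibble(classes)[c("gene_id", "class")], by = "gene_id")
  if (dplyr::n_distinct(d$class) < 2L) abort("need >= 2 populated classes")
  summary <- d |> group_by(.data$index, .data$class) |>
    summarise(n = dplyr::n(),
              q1 = quantile(.data$rate, 0.25, names = FALSE),
              median = median(.data$rate),
              q3 = quantile(.data$rate, 0.75, names = FALSE),
              .groups = "drop")
  lo <- min(d$class); hi <- max(d$class)
  tests <- d |> group_by(.data$index) |>
    summarise(res = list(wilcoxon_rank_sum(.data$rate[.data$class == hi],
                                           .data$rate[.data$class == lo])),
              .groups = "drop") |>
    tidyr::unnest("res") |>
    mutate(class_high = hi, class_low = lo) |>
    select("index", "class_high", "class_low", "statistic", "p_value",
           "n1", "n2")
  structure(list(summary = summary, tests = tests),
            class = "turnover_distributions")
}

#' @export
print.turnover_distributions <- function(x, ...) {
  cat("<turnover_distributions>\n$summary:\n")
  print(x$summary)
  cat("$tests (top vs bottom class):\n")
  print(x$tests)
  invisible(x)
}

#' Probe-wise correlation of turnover with a modification
#'
#' For every probe with a turnover estimate, the mean modification signal
#' inside the probe interval is computed and the Spearman correlation of
#' modification level against turnover rate across probes is returned.
#'
#' @param probes probe tibble with `rate`.
#' @param mod_track unstranded modification track.
#' @return one-row tibble as [spearman_cor()].
#' @export
turnover_modification_correlation <- function(probes, mod_track) {
  pr <- probes |> filter(!is.na(.data$rate),
                         .data$chrom %in% track_chroms(mod_track))
  mod <- purrr::map_dbl(seq_len(nrow(pr)), function(i) {
    v <- window_values_at(mod_track, pr$chrom[i], pr$start[i], "+",
                          0L, pr$end[i] - pr$start[i], "unstranded")
    if (all(is.na(v))) NA_real_ else mean(v, na.rm = TRUE)
  })
  ok <- !is.na(mod)
  if (sum(ok) < 3L) abort("need >= 3 probes with both values")
  spearman_cor(mod[ok], pr$rate[ok])
}
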