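#' Nucleosome-depleted-region size per gene
#'
#' The NDR is the gap between the -1 and +1 nucleosomes. `mode = "edge"`
#' (default) measures edge-to-edge: the distance between the two call
#' intervals, floored at 0 when they touch or overlap, so an NDR is a
#' non-negative depleted span rather than a signed offset. `mode = "dyad"`
#' measures between interval midpoints instead (adding roughly one
#' nucleosome width). Sizes are strand-symmetric: a `-` strand gene with
#' mirrored calls gets the same size as its `+` mirror. Genes missing
#' either call are skipped, with the reason recorded in the `"skipped"`
#' attribute.
#'
#' @param map a [nucleosome_map].
#' @param genes gene tibble (used to restrict and order the output; genes
#'   absent from `map` are skipped).
#' @param mode `"edge"` or `"dyad"`.
#' @return tibble `gene_id`, `ndr_size` (bp), `minus1_start`, `minus1_end`,
#'   `plus1_start`, `plus1_end`; skipped genes in `attr(, "skipped")`.
#' @export
ndr_sizes <- function(map, genes, mode = c("edge", "dyad")) {
  mode <- match.arg(mode)
  m1 <- map |> filter(.data$index == -1L) |>
    select("gene_id", minus1_start = "start", minus1_end = "end")
  p1 <- map |> filter(.data$index == 1L) |>
    select("gene_id", plus1_start = "start", plus1_end = "end")
  joined <- tibble(gene_id = genes$gene_id) |>
    left_join(m1, by = "gene_id") |> left_join(p1, by = "gene_id")
  has_both <- !is.na(joined$minus1_start) & !is.na(joined$plus1_start)
  skipped <- tibble(
    gene_id = joined$gene_id[!has_both],
    reason = case_when(
      is.na(joined$minus1_start[!has_both]) &
        is.na(joined$plus1_start[!has_both]) ~ "missing -1 and +1",
      is.na(joined$minus1_start[!has_both]) ~ "missing -1",
      TRUE ~ "missing +1"))
  out <- joined[has_both, ]
  if (mode == "edge") {
    gap <- pmax(out$minus1_start, out$plus1_start) -
      pmin(out$minus1_end, out$plus1_end)
    out$ndr_size <- pmax(0, gap)
  } else {
    out$ndr_size <- abs((out$plus1_start + out$plus1_end) / 2 -
                          (out$minus1_start + out$minus1_end) / 2)
  }
  out <- out |> select("gene_id", "ndr_size", dplyr::everything())
  attr(out, "skipped") <- skipped
  out
}

#' Median NDR size per gene group, with an optional two-group contrast
#'
#' Medians use midpoint averaging for even counts. When `contrast` names
#' two groups, their NDR size distributions are additionally compared with
#' the two-sided Wilcoxon rank-sum test; the result is stored in the
#' `"contrast"` attribute.
#'
#' @param records output of [ndr_sizes()].
#' @param groups tibble `gene_id`, `group` (e.g. a tidied
#'   [class_assignment]).
#' @param contrast optional length-2 vector of group names to compare.
#' @return tibble `group`, `n`, `median_ndr`.
#' @export
group_median_ndr <- function(records, groups, contrast = NULL) {
  stopifnot(all(c("gene_id", "group") %in% names(groups)))
  d <- records |> inner_join(groups, by = "gene_id")
  out <- d |> group_by(.data$group) |>
    summarise(n = dplyr::n(), median_ndr = median(.data$ndr_size),
              .groups = "drop")
  if (!is.null(contrast)) {
    stopifnot(length(contrast) == 2L)
    a <- d$ndr_size[d$group == contrast[1L]]
    b <- d$ndr_size[d$group == contrast[2L]]
    if (!length(a) || !length(b)) abort("contrast group without records")
    attr(out, "contrast") <- wilcoxon_rank_sum(a, b) |>
      mutate(group_a = contrast[1L], group_b = contrast[2L])
  }
  out
}
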