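#' Group genes by antisense class shift between strains
#'
#' Genes are grouped by how their antisense class changes in a mutant
#' relative to wild-type, on the shared wild-type class scale (see
#' [reassign_classes()]): *increased* means up by at least two classes,
#' *decreased* down by at least two, *unchanged* exactly the same class.
#' Genes shifting by exactly one class match none of the three definitions
#' and are kept in an explicit *excluded* group so the four groups always
#' partition the classified genes. Genes present in only one assignment are
#' dropped and listed in `attr(, "unmatched")`.
#'
#' @param wt,mut [class_assignment]s for wild-type and mutant.
#' @param strain optional strain label stored on the result.
#' @return a `shift_groups` tibble: `gene_id`, `wt_class`, `mut_class`,
#'   `shift`, `group`.
#' @export
group_by_shift <- function(wt, mut, strain = NULL) {
  w <- as_tibble(wt)[c("gene_id", "class")] |> rename(wt_class = "class")
  m <- as_tibble(mut)[c("gene_id", "class")] |> rename(mut_class = "class")
  unmatched <- c(setdiff(w$gene_id, m$gene_id), setdiff(m$gene_id, w$gene_id))
  d <- inner_join(w, m, by = "gene_id") |>
    mutate(shift = .data$mut_class - .data$wt_class,
           group = case_when(.data$shift >= 2L ~ "increased",
                             .data$shift <= -2L ~ "decreased",
                             .data$shift == 0L ~ "unchanged",
                             TRUE ~ "excluded"))
  structure(d, class = c("shift_groups", class(d)),
            strain = strain, unmatched = unmatched)
}

#' @rdname group_by_shift
#' @param x a `shift_groups`.
#' @param ... unused.
#' @method glance shift_groups
#' @export
glance.shift_groups <- function(x, ...) {
  tibble(strain = attr(x, "strain") %||% NA_character_,
         n_increased = sum(x$group == "increased"),
         n_decreased = sum(x$group == "decreased"),
         n_unchanged = sum(x$group == "unchanged"),
         n_excluded = sum(x$group == "excluded"))
}

#' @export
print.shift_groups <- function(x, ...) {
  g <- glance.shift_groups(x)
  cat(sprintf(
    "<shift_groups%s: %d increased / %d decreased / %d unchanged / %d excluded>\n",
    if (!is.na(g$strain)) paste0(" [", g$strain, "]") else "",
    g$n_increased, g$n_decreased, g$n_unchanged, g$n_excluded))
  NextMethod()
}

#' Mutant-minus-wild-type difference metagene per shift group
#'
#' For each shift group, the TSS-anchored mean profile in the mutant minus
#' the same profile in wild-type (positive = level went up in the mutant).
#' At each configured test position, per-gene differences are compared
#' between the increased (and decreased) group and the unchanged group with
#' the two-sided Wilcoxon rank-sum test. Empty groups are omitted and
#' listed in `attr(, "omitted")`. Modification tracks should be normalised
#' (e.g. to H3/occupancy) before calling.
#'
#' @param genes gene tibble.
#' @param shifts a [group_by_shift()] result.
#' @param wt_track,mut_track matching [genome_track][stranded_track]s.
#' @param range,bin,strand_mode as [metagene_profile()].
#' @param test_positions bp relative to TSS at which between-group tests are
#'   run (snapped to bin starts); defaults to the promoter (0) and a
#'   mid-body position (+600).
#' @return a `difference_profile` list: `$profile` (tibble `position`,
#'   `group`, `difference`, `n_genes`) and `$tests` (tibble `position`,
#'   `group`, `p_value`, ...).
#' @export
difference_profile <- function(genes, shifts, wt_track, mut_track,
                               range = c(-1000L, 1500L), bin = 10L,
                               strand_mode = "unstranded",
                               test_positions = c(0L, 600L)) {
  groups <- split(shifts$gene_id, shifts$group)
  groups <- groups[setdiff(names(groups), "excluded")]
  omitted <- names(groups)[lengths(groups) == 0L]
  groups <- groups[lengths(groups) > 0L]
  sub <- genes |> filter(.data$gene_id %in% unlist(groups))
  mw <- gene_bin_matrix(sub, wt_track, range, bin, strand_mode, "mean")
  mm <- gene_bin_matrix(sub, mut_track, range, bin, strand_mode, "mean")
  diff_mat <- mm - mw
  positions <- as.integer(colnames(diff_mat))
  profile <- purrr::imap(groups, function(ids, nm) {
    dsub <- diff_mat[match(ids, sub$gene_id), , drop = FALSE]
    tibble(position = positions, group = nm,
           difference = unname(colMeans(dsub, na.rm = TRUE)),
           n_genes = unname(colSums(!is.na(dsub))))
  }) |> bind_rows()
  profile$difference[is.nan(profile$difference)] <- NA_real_
  tests <- NULL
  if ("unchanged" %in% names(groups)) {
    ref <- diff_mat[match(groups$unchanged, sub$gene_id), , drop = FALSE]
    snapped <- positions[pmin(pmax(findInterval(test_positions, positions), 1L),
                              length(positions))]
    tests <- purrr::map(setdiff(names(groups), "unchanged"), function(nm) {
      gm <- diff_mat[match(groups[[nm]], sub$gene_id), , drop = FALSE]
      purrr::map(snapped, function(p) {
        j <- match(p, positions)
        va <- gm[, j]; vb <- ref[, j]
        res <- wilcoxon_rank_sum(va[!is.na(va)], vb[!is.na(vb)])
        res |> mutate(position = p, group = nm)
      }) |> bind_rows()
    }) |> bind_rows() |>
      select("position", "group", "statistic", "p_value", "method",
             "n1", "n2")
  }
  structure(list(profile = profile, tests = tests),
            class = "difference_profile", omitted = omitted)
}

#' @export
print.difference_profile <- function(x, ...) {
  cat("<difference_profile>\n$profile:\n")
  print(x$profile)
  if (!is.null(x$tests)) {
    cat("$tests (vs unchanged):\n")
    print(x$tests)
  }
  invisible(x)
}

#' Correlation of sense changes with antisense changes
#'
#' Per gene, the mutant-minus-wild-type change in sense and in antisense
#' window counts; the Spearman correlation between the two changes says
#' whether altering antisense transcription is accompanied by systematic
#' sense changes. When either change vector is constant (e.g. mutant equals
#' wild-type exactly) the correlation is flagged undefined.
#'
#' @param wt_counts,mut_counts tibbles `gene_id`, `sense`, `antisense`.
#' @return a `shift_scatter` list: `$deltas` (tibble `gene_id`, `d_sense`,
#'   `d_antisense`) and `$correlation` ([spearman_cor()] row).
#' @export
shift_vs_sense_scatter <- function(wt_counts, mut_counts) {
  d <- inner_join(wt_counts, mut_counts, by = "gene_id",
                  suffix = c("_wt", "_mut")) |>
    mutate(d_sense = .data$sense_mut - .data$sense_wt,
           d_antisense = .data$antisense_mut - .data$antisense_wt) |>
    select("gene_id", "d_sense", "d_antisense")
  structure(list(deltas = d,
                 correlation = spearman_cor(d$d_sense, d$d_antisense)),
            class = "shift_scatter")
}

#' @export
print.shift_scatter <- function(x, ...) {
  r <- x$correlation
  cat(sprintf("<shift_scatter: n = %d, r_s(d_sense, d_antisense) = %s>\n",
              r$n, if (r$defined) sprintf("%.3f", r$rho) else "undefined"))
  invisible(x)
}
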