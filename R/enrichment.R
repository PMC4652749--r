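#' Promoter factor enrichment between two gene groups
#'
#' For every factor column of the occupancy matrix, compares occupancy in
#' group A genes against group B genes with the two-sided Wilcoxon rank-sum
#' test, determines the direction by comparing group medians, and flags a
#' factor as *enriched* when it is higher in group A and its p-value falls
#' below `alpha`. No multiple-testing correction is applied: the procedure
#' uses a single hard raw-p cutoff (default 1e-4), which should be kept in
#' mind when interpreting counts of enriched factors. Missing occupancy
#' values are dropped per factor; factors with fewer than 2 observations in
#' either group are excluded (listed in `attr(, "excluded")`).
#'
#' @param occupancy wide tibble from [read_occupancy_matrix()]: `gene_id`
#'   plus one numeric column per factor.
#' @param group_a,group_b disjoint character vectors of gene ids, each
#'   contributing at least 2 genes with data.
#' @param alpha enrichment p-value cutoff.
#' @param factor_info optional tibble `factor`, `complex` merged into the
#'   output.
#' @return an `enrichment_table` tibble sorted by ascending p-value:
#'   `factor`, (`complex`,) `p_value`, `direction`, `enriched`, `n1`, `n2`;
#'   attributes record the comparison metadata.
#' @export
factor_enrichment <- function(occupancy, group_a, group_b, alpha = 1e-4,
                              factor_info = NULL) {
  if (length(intersect(group_a, group_b))) abort("groups must be disjoint")
  ia <- occupancy$gene_id %in% group_a
  ib <- occupancy$gene_id %in% group_b
  factors <- setdiff(names(occupancy), "gene_id")
  rows <- vector("list", length(factors))
  excluded <- character(0)
  for (k in seq_along(factors)) {
    f <- factors[k]
    va <- occupancy[[f]][ia]; va <- va[!is.na(va)]
    vb <- occupancy[[f]][ib]; vb <- vb[!is.na(vb)]
    if (length(va) < 2L || length(vb) < 2L) {
      excluded <- c(excluded, f)
      next
    }
    res <- wilcoxon_rank_sum(va, vb)
    dir <- if (median(va) > median(vb)) "higher-in-A" else "higher-in-B"
    rows[[k]] <- tibble(factor = f, p_value = res$p_value, direction = dir,
                        enriched = dir == "higher-in-A" & res$p_value < alpha,
                        n1 = res$n1, n2 = res$n2)
  }
  out <- bind_rows(rows) |> arrange(.data$p_value)
  if (!is.null(factor_info))
    out <- out |> left_join(factor_info, by = "factor") |>
      select("factor", "complex", dplyr::everything())
  structure(out, class = c("enrichment_table", class(out)),
            alpha = alpha, excluded = excluded,
            n_group_a = length(group_a), n_group_b = length(group_b))
}

#' @rdname factor_enrichment
#' @param x an `enrichment_table`.
#' @param ... unused.
#' @method glance enrichment_table
#' @export
glance.enrichment_table <- function(x, ...) {
  tibble(n_factors = nrow(x), n_enriched = sum(x$enriched),
         alpha = attr(x, "alpha"),
         n_group_a = attr(x, "n_group_a"), n_group_b = attr(x, "n_group_b"))
}

#' @export
print.enrichment_table <- function(x, ...) {
  cat(sprintf(
    "<enrichment_table: %d factors, %d enriched at p < %g (A n=%d vs B n=%d)>\n",
    nrow(x), sum(x$enriched), attr(x, "alpha"),
    attr(x, "n_group_a"), attr(x, "n_group_b")))
  NextMethod()
}
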