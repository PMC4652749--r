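#' TSS-anchored bin matrix
#'
#' Internal workhorse shared by the profiling functions: for every gene, the
#' per-bin summary (mean for ChIP-style signal, sum for count tracks) of
#' track signal in fixed-width bins tiling `[range[1], range[2])` relative
#' to the TSS, orientation-corrected. Bins whose positions are entirely off
#' the chromosome (or all-missing) are `NA`.
#'
#' @param genes gene tibble.
#' @param track a [genome_track][stranded_track].
#' @param range half-open relative window, default `c(-1000, 1500)`.
#' @param bin bin width in bp.
#' @param strand_mode passed to [window_values()].
#' @param stat `"mean"` (ChIP-style tracks) or `"sum"` (count tracks).
#' @return numeric matrix, genes x bins; columns named by bin start.
#' @keywords internal
gene_bin_matrix <- function(genes, track, range = c(-1000L, 1500L), bin = 10L,
                            strand_mode = "unstranded", stat = c("mean", "sum")) {
  stat <- match.arg(stat)
  span <- range[2L] - range[1L]
  nbin <- span %/% bin
  if (nbin < 1L) abort("range shorter than one bin")
  m <- matrix(NA_real_, nrow = nrow(genes), ncol = nbin,
              dimnames = list(genes$gene_id,
                              range[1L] + bin * (seq_len(nbin) - 1L)))
  grp <- rep(seq_len(nbin), each = bin)
  for (i in seq_len(nrow(genes))) {
    v <- window_values_at(track, genes$chrom[i], genes$tss[i], genes$strand[i],
                          range[1L], range[1L] + nbin * bin, strand_mode)
    vm <- matrix(v, nrow = bin)
    if (stat == "mean") {
      s <- colSums(vm, na.rm = TRUE)
      k <- colSums(!is.na(vm))
      m[i, ] <- ifelse(k > 0L, s / k, NA_real_)
    } else {
      m[i, ] <- colSums(vm, na.rm = TRUE) + ifelse(colSums(!is.na(vm)) > 0L,
                                                   0, NA_real_)
    }
  }
  m
}

#' Average metagene profile per gene group
#'
#' The classic TSS-anchored average: for each bin, the mean over genes of
#' each gene's mean signal in that bin, separately per group. Missing
#' positions are excluded from both numerator and denominator, so chromosome
#' ends do not drag profiles toward zero.
#'
#' @param genes gene tibble; grouping comes from `group`, either a column
#'   name in `genes` or a named list of gene-id vectors. `NULL` profiles all
#'   genes as one group.
#' @inheritParams gene_bin_matrix
#' @return a `metagene_profile` tibble: `position` (bin start, bp relative
#'   to TSS), `group`, `value`, `n_genes`.
#' @export
metagene_profile <- function(genes, track, group = NULL,
                             range = c(-1000L, 1500L), bin = 10L,
                             strand_mode = "unstranded",
                             stat = c("mean", "sum")) {
  stat <- match.arg(stat)
  groups <- resolve_groups(genes, group)
  mat <- gene_bin_matrix(genes, track, range, bin, strand_mode, stat)
  out <- purrr::imap(groups, function(ids, nm) {
    sub <- mat[match(ids, genes$gene_id), , drop = FALSE]
    tibble(position = as.integer(colnames(mat)),
           group = nm,
           value = unname(colMeans(sub, na.rm = TRUE)),
           n_genes = unname(colSums(!is.na(sub))))
  }) |> bind_rows()
  out$value[is.nan(out$value)] <- NA_real_
  structure(out, class = c("metagene_profile", class(out)),
            bin = bin, stat = stat)
}

resolve_groups <- function(genes, group) {
  if (is.null(group)) return(list(all = genes$gene_id))
  if (is.character(group) && length(group) == 1L && group %in% names(genes)) {
    return(split(genes$gene_id, genes[[group]]))
  }
  if (is.list(group) && !is.null(names(group))) {
    missing <- setdiff(unique(unlist(group)), genes$gene_id)
    if (length(missing))
      abort(paste0("group gene ids absent from `genes`: ", missing[1L], " ..."))
    return(group)
  }
  abort("`group` must be NULL, a column name, or a named list of gene ids")
}

#' Per-position correlation of a track with sense/antisense transcription
#'
#' At every bin around the TSS, the Spearman correlation across genes
#' between the gene's bin signal and its windowed nascent count, computed
#' separately against sense and antisense counts. Bins that are constant
#' across genes yield a flagged-undefined (NA) coefficient.
#'
#' @inheritParams metagene_profile
#' @param counts tibble with `gene_id`, `sense`, `antisense` window counts.
#' @return a `correlation_profile` tibble: `position`, `target`
#'   (sense/antisense), `rho`, `n`.
#' @export
correlation_profile <- function(genes, track, counts,
                                range = c(-1000L, 1500L), bin = 10L,
                                strand_mode = "unstranded",
                                stat = c("mean", "sum")) {
  stopifnot(all(c("gene_id", "sense", "antisense") %in% names(counts)))
  stat <- match.arg(stat)
  mat <- gene_bin_matrix(genes, track, range, bin, strand_mode, stat)
  idx <- match(genes$gene_id, counts$gene_id)
  if (anyNA(idx)) abort("counts missing for some genes")
  targets <- list(sense = counts$sense[idx], antisense = counts$antisense[idx])
  out <- purrr::imap(targets, function(ct, nm) {
    res <- apply(mat, 2L, function(col) {
      ok <- !is.na(col) & !is.na(ct)
      if (sum(ok) < 3L) return(c(NA_real_, sum(ok)))
      s <- spearman_cor(col[ok], ct[ok])
      c(if (s$defined) s$rho else NA_real_, s$n)
    })
    tibble(position = as.integer(colnames(mat)), target = nm,
           rho = unname(res[1L, ]), n = as.integer(unname(res[2L, ])))
  }) |> bind_rows()
  structure(out, class = c("correlation_profile", class(out)), bin = bin)
}

#' Group contrast at the profile extremum near the TSS
#'
#' Locates the bin where the mean profile attains its maximum (or, for
#' dip-shaped signals such as nucleosome occupancy over the NDR, its
#' minimum) within a vicinity of the TSS, then compares the two groups'
#' per-gene signal at that single bin with the two-sided Wilcoxon rank-sum
#' test. By default the extremum is found on the pooled mean of both
#' groups; `extremum_on = "group_a"` uses group A's own profile instead.
#'
#' @inheritParams metagene_profile
#' @param group_a,group_b character vectors of gene ids.
#' @param polarity `"max"` or `"min"`.
#' @param vicinity relative window searched for the extremum, default
#'   `c(-300, 300)`.
#' @param extremum_on `"pooled"` or `"group_a"`.
#' @return one-row tibble: `position`, `polarity`, `statistic`, `p_value`,
#'   `method`, `n1`, `n2`.
#' @export
extremum_group_test <- function(genes, track, group_a, group_b,
                                polarity = c("max", "min"),
                                vicinity = c(-300L, 300L), bin = 10L,
                                strand_mode = "unstranded",
                                extremum_on = c("pooled", "group_a")) {
  polarity <- match.arg(polarity)
  extremum_on <- match.arg(extremum_on)
  if (!length(group_a) || !length(group_b)) abort("both groups must be non-empty")
  sub <- genes |> filter(.data$gene_id %in% c(group_a, group_b))
  if (!all(c(group_a, group_b) %in% sub$gene_id))
    abort("group gene ids absent from `genes`")
  mat <- gene_bin_matrix(sub, track, vicinity, bin, strand_mode, "mean")
  pick_from <- if (extremum_on == "pooled") sub$gene_id else group_a
  pooled <- colMeans(mat[match(pick_from, sub$gene_id), , drop = FALSE],
                     na.rm = TRUE)
  if (all(is.na(pooled))) abort("no signal inside the vicinity")
  j <- if (polarity == "max") which.max(pooled) else which.min(pooled)
  va <- mat[match(group_a, sub$gene_id), j]
  vb <- mat[match(group_b, sub$gene_id), j]
  res <- wilcoxon_rank_sum(va[!is.na(va)], vb[!is.na(vb)])
  tibble(position = as.integer(colnames(mat)[j]), polarity = polarity,
         statistic = res$statistic, p_value = res$p_value,
         method = res$method, n1 = res$n1, n2 = res$n2)
}
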