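#' Remove dubious and considerably-overlapping genes
#'
#' Drops genes flagged `dubious`, then removes *both* members of every gene
#' pair whose genomic intervals overlap by more than `overlap_limit` bp
#' (strand-blind). The surviving set is returned ordered by chromosome and
#' start. The default limit of 0 removes any overlapping pair, which is the
#' strictest reading of excluding overlapping convergent genes from a
#' TSS-proximal counting window; the limit is exposed because "considerable"
#' overlap has no canonical cutoff.
#'
#' @param genes gene tibble (see [read_genes()]).
#' @param overlap_limit maximum tolerated pairwise overlap in bp.
#' @return filtered gene tibble.
#' @export
filter_genes <- function(genes, overlap_limit = 0L) {
  g <- genes |> filter(!.data$dubious)
  if (nrow(g) > 1L) {
    ir <- GenomicRanges::GRanges(g$chrom, IRanges::IRanges(g$start + 1L, g$end))
    hits <- GenomicRanges::findOverlaps(ir, minoverlap = overlap_limit + 1L,
                                        drop.self = TRUE, drop.redundant = TRUE,
                                        ignore.strand = TRUE)
    bad <- unique(c(S4Vectors::queryHits(hits), S4Vectors::subjectHits(hits)))
    if (length(bad)) g <- g[-bad, ]
  }
  g |> arrange(.data$chrom, .data$start)
}

#' Count nascent reads in the TSS-anchored window
#'
#' Sums per-base NET-seq signal in the half-open window
#' `[rel_start, rel_end)` downstream of the sense TSS (default the 300 bp
#' classification window), on the sense or antisense strand of each gene.
#'
#' @param genes gene tibble.
#' @param netseq stranded [genome_track][stranded_track] of per-base read
#'   counts.
#' @param strand_mode `"antisense"` (default) or `"sense"`.
#' @param rel_start,rel_end window bounds relative to the TSS.
#' @return tibble `gene_id`, `count`.
#' @export
count_window_reads <- function(genes, netseq,
                               strand_mode = c("antisense", "sense"),
                               rel_start = 0L, rel_end = 300L) {
  strand_mode <- match.arg(strand_mode)
  counts <- purrr::map_dbl(seq_len(nrow(genes)), function(i) {
    v <- window_values_at(netseq, genes$chrom[i], genes$tss[i],
                          genes$strand[i], rel_start, rel_end, strand_mode)
    sum(v, na.rm = TRUE)
  })
  tibble(gene_id = genes$gene_id, count = counts)
}

#' Assign five antisense (or sense) transcription classes
#'
#' Class 1 is fixed by absolute counts: exactly the genes with 0 or 1 read
#' in the window. The remaining genes are ranked by count and split into
#' four groups of as-equal-as-possible size (classes 2-5, increasing count).
#' All genes sharing a count value receive the same class: a tie block
#' straddling a split boundary goes entirely to the lower class, which keeps
#' the assignment deterministic and order-independent. The four class
#' boundaries (the minimum count of classes 2-5, lower-inclusive) are
#' recorded so mutant libraries can be mapped onto the same scale with
#' [reassign_classes()].
#'
#' @param counts tibble with `gene_id` and `count` columns.
#' @return a `class_assignment`: tibble `gene_id`, `count`, `class`, with
#'   attributes `boundaries` (named numeric, length 4) and `window`.
#' @export
assign_five_classes <- function(counts) {
  stopifnot(all(c("gene_id", "count") %in% names(counts)))
  if (any(counts$count < 0)) abort("negative counts")
  rest <- counts |> filter(.data$count > 1)
  n_distinct_rest <- dplyr::n_distinct(rest$count)
  if (n_distinct_rest < 4L)
    abort(sprintf(
      "too few distinct counts above 1 to form 5 classes (achievable: %d)",
      1L + n_distinct_rest))
  if (nrow(rest) < 5L) abort("need >= 5 genes with count > 1")
  rest <- rest |> arrange(.data$count, .data$gene_id)
  m <- nrow(rest)
  provisional <- 1L + ceiling(seq_len(m) * 4L / m)      # 2..5 by rank
  # same count value => same (lowest provisional) class
  block_class <- tapply(provisional, rest$count, min)
  rest$class <- as.integer(block_class[as.character(rest$count)])
  out <- counts |>
    left_join(rest |> select("gene_id", "class"), by = "gene_id") |>
    mutate(class = ifelse(.data$count <= 1, 1L, .data$class))
  boundaries <- vapply(2:5, function(k) {
    v <- out$count[out$class == k]
    if (length(v)) min(v) else NA_real_
  }, numeric(1))
  names(boundaries) <- paste0("class", 2:5)
  new_class_assignment(out, boundaries)
}

new_class_assignment <- function(tbl, boundaries, window = c(0L, 300L)) {
  tbl <- as_tibble(tbl)[c("gene_id", "count", "class")]
  structure(tbl, boundaries = boundaries, window = window,
            class = c("class_assignment", class(tbl)))
}

#' @export
print.class_assignment <- function(x, ...) {
  b <- attr(x, "boundaries")
  cat(sprintf("<class_assignment: %d genes; class boundaries (min count) %s>\n",
              nrow(x), paste(names(b), b, sep = "=", collapse = ", ")))
  NextMethod()
}

#' @rdname assign_five_classes
#' @param x a `class_assignment`.
#' @param ... unused.
#' @method tidy class_assignment
#' @export
tidy.class_assignment <- function(x, ...) {
  as_tibble(x)[c("gene_id", "count", "class")]
}

#' @rdname assign_five_classes
#' @method glance class_assignment
#' @export
glance.class_assignment <- function(x, ...) {
  sizes <- tabulate(x$class, 5L)
  out <- tibble(n_genes = nrow(x))
  for (k in 1:5) out[[paste0("n_class", k)]] <- sizes[k]
  b <- attr(x, "boundaries")
  for (nm in names(b)) out[[paste0("min_count_", nm)]] <- b[[nm]]
  out
}

#' Map counts onto an existing class scale
#'
#' Assigns each gene a class using the boundaries recorded in a wild-type
#' [assign_five_classes()] result, without re-splitting: count <= 1 is
#' always class 1; otherwise the class is the highest one whose
#' lower-inclusive boundary the count reaches (a count exactly at a boundary
#' belongs to the class above it). Counts above 1 but below the class-2
#' boundary are clamped to class 2.
#'
#' @param counts tibble `gene_id`, `count` (e.g. a mutant library).
#' @param wt_assignment the wild-type `class_assignment`.
#' @return a `class_assignment` on the wild-type scale.
#' @export
reassign_classes <- function(counts, wt_assignment) {
  if (any(counts$count < 0)) abort("negative counts")
  b <- attr(wt_assignment, "boundaries")
  cls <- rep(2L, nrow(counts))
  for (k in 2:5) {                      # boundaries are lower-inclusive
    bk <- b[[paste0("class", k)]]
    if (!is.na(bk)) cls[counts$count >= bk] <- k
  }
  cls[counts$count <= 1] <- 1L
  new_class_assignment(tibble(gene_id = counts$gene_id,
                              count = counts$count, class = cls),
                       b, attr(wt_assignment, "window"))
}

#' Cross-tabulated sense/antisense gene groups
#'
#' Defines named gene groups by predicates over the per-gene sense and
#' antisense window counts (e.g. high antisense with low sense), the logic
#' behind joint promoter-architecture contrasts. Each predicate is an
#' expression in the variables `sense` and `antisense`.
#'
#' @param counts tibble with `gene_id`, `sense`, `antisense` columns.
#' @param ... named predicate expressions, e.g.
#'   `high_as = antisense >= 28 & sense < 100`.
#' @return tibble: `group`, `n`, `median_sense`, `median_antisense`, and a
#'   `genes` list-column of member gene ids. Empty groups are retained with
#'   `n = 0` and `NA` medians.
#' @export
joint_sense_antisense_groups <- function(counts, ...) {
  stopifnot(all(c("gene_id", "sense", "antisense") %in% names(counts)))
  specs <- rlang::enquos(...)
  if (!length(specs) || is.null(names(specs)) || any(names(specs) == ""))
    abort("supply named group predicates")
  purrr::imap(specs, function(q, nm) {
    keep <- rlang::eval_tidy(q, data = counts)
    keep[is.na(keep)] <- FALSE
    sub <- counts[keep, ]
    tibble(group = nm, n = nrow(sub),
           median_sense = if (nrow(sub)) median(sub$sense) else NA_real_,
           median_antisense = if (nrow(sub)) median(sub$antisense) else NA_real_,
           genes = list(sub$gene_id))
  }) |> bind_rows()
}

#' Write / read a class assignment as TSV (+ JSON boundary sidecar)
#'
#' @param assignment a `class_assignment`.
#' @param path output TSV; boundaries go to `<path>.json`.
#' @return `path`, invisibly.
#' @export
write_class_assignment <- function(assignment, path) {
  readr::write_tsv(tidy.class_assignment(assignment), path)
  jsonlite::write_json(
    list(boundaries = as.list(attr(assignment, "boundaries")),
         window = attr(assignment, "window")),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}
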