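#' Read gene annotations
#'
#' Reads BED6 or GFF3 gene annotations into a tibble with one row per gene.
#' Coordinates are normalised to 0-based half-open `[start, end)` (GFF3's
#' 1-based inclusive starts are shifted on read; BED is native). The sense
#' TSS and TES are derived from the strand: on `+`, `tss = start` and
#' `tes = end - 1`; on `-`, `tss = end - 1` and `tes = start`.
#'
#' GFF3 attribute fields are preserved as extra character columns; a
#' `dubious` attribute (`true`/`false`) becomes a logical column, defaulting
#' to `FALSE` (BED carries no attributes). A `hypothetical_tss` attribute is
#' likewise kept as a flag; this reader never assigns hypothetical TSSs
#' itself.
#'
#' @param path annotation file.
#' @param dialect `"bed"` (BED6) or `"gff3"`.
#' @return tibble with columns `gene_id`, `chrom`, `start`, `end`, `strand`,
#'   `tss`, `tes`, `dubious`, plus any attribute columns.
#' @export
read_genes <- function(path, dialect = c("bed", "gff3")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  if (dialect == "bed") {
    check_bed_lines(path, min_fields = 6L)
    gr <- rtracklayer::import(path, format = "BED")
    g <- tibble(
      gene_id = as.character(S4Vectors::mcols(gr)$name),
      chrom = as.character(GenomicRanges::seqnames(gr)),
      start = GenomicRanges::start(gr) - 1L,
      end = GenomicRanges::end(gr),
      strand = as.character(GenomicRanges::strand(gr)),
      dubious = FALSE
    )
  } else {
    gr <- rtracklayer::import(path, format = "GFF3")
    mc <- as.data.frame(S4Vectors::mcols(gr))
    if ("type" %in% names(mc) && any(mc$type == "gene")) {
      keep <- mc$type == "gene"
      gr <- gr[keep]
      mc <- mc[keep, , drop = FALSE]
    }
    id <- mc$ID %||% mc$Name
    if (is.null(id)) abort("GFF3 gene records need an ID or Name attribute")
    g <- tibble(
      gene_id = as.character(id),
      chrom = as.character(GenomicRanges::seqnames(gr)),
      start = GenomicRanges::start(gr) - 1L,
      end = GenomicRanges::end(gr),
      strand = as.character(GenomicRanges::strand(gr)),
      dubious = tolower(as.character(mc$dubious %||% "false")) %in%
        c("true", "1", "yes")
    )
    extra <- setdiff(names(mc), c("source", "type", "score", "phase",
                                  "ID", "Name", "dubious"))
    for (col in extra) g[[col]] <- as.character(mc[[col]])
  }
  if (!all(g$strand %in% c("+", "-")))
    abort(sprintf("unknown strand symbol '%s' in %s",
                  setdiff(g$strand, c("+", "-"))[1L], path))
  if (any(g$start >= g$end)) abort("gene with start >= end")
  g |>
    mutate(tss = ifelse(.data$strand == "+", .data$start, .data$end - 1L),
           tes = ifelse(.data$strand == "+", .data$end - 1L, .data$start)) |>
    select("gene_id", "chrom", "start", "end", "strand", "tss", "tes",
           "dubious", dplyr::everything())
}

check_bed_lines <- function(path, min_fields) {
  lines <- readLines(path, warn = FALSE)
  body <- !grepl("^(#|track|browser)", lines) & nzchar(lines)
  nf <- vapply(strsplit(lines[body], "[\t ]+"), length, integer(1))
  bad <- which(nf < min_fields)
  if (length(bad))
    abort(sprintf("malformed line %d in %s: %d field(s), need >= %d",
                  which(body)[bad[1L]], path, nf[bad[1L]], min_fields))
  invisible(TRUE)
}

#' Write gene annotations as BED6
#'
#' @param genes a gene tibble (see [read_genes()]).
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_genes_bed <- function(genes, path) {
  readr::write_tsv(
    tibble(chrom = genes$chrom, start = genes$start, end = genes$end,
           name = genes$gene_id, score = 0L, strand = genes$strand),
    path, col_names = FALSE)
  invisible(path)
}

#' Read nucleosome calls with gene-relative indices
#'
#' The expected format is BED-like TSV: `chrom start end gene_id index`,
#' where `index` is the nucleosome's position relative to the TSS (-1 is the
#' promoter-proximal upstream nucleosome, +1 the first downstream, up to +4).
#' Coordinates are 0-based half-open.
#'
#' @param path input file.
#' @return a `nucleosome_map` tibble: `gene_id`, `index`, `chrom`, `start`,
#'   `end`.
#' @export
read_nucleosome_calls <- function(path) {
  check_bed_lines(path, min_fields = 5L)
  d <- readr::read_tsv(path, col_names = c("chrom", "start", "end",
                                           "gene_id", "index"),
                       col_types = "ciici", progress = FALSE)
  nucleosome_map(d$gene_id, d$index, d$chrom, d$start, d$end)
}

#' @rdname read_nucleosome_calls
#' @param gene_id,index,chrom,start,end vectors of equal length describing
#'   one nucleosome call each.
#' @export
nucleosome_map <- function(gene_id, index, chrom, start, end) {
  stopifnot(all(end > start), all(index != 0L))
  out <- tibble(gene_id = as.character(gene_id), index = as.integer(index),
                chrom = as.character(chrom), start = as.integer(start),
                end = as.integer(end))
  if (anyDuplicated(out[c("gene_id", "index")]))
    abort("duplicate (gene, index) nucleosome call")
  class(out) <- c("nucleosome_map", class(out))
  out
}

#' @rdname read_nucleosome_calls
#' @param map a `nucleosome_map`.
#' @export
write_nucleosome_calls <- function(map, path) {
  readr::write_tsv(tibble(chrom = map$chrom, start = map$start, end = map$end,
                          gene_id = map$gene_id, index = map$index),
                   path, col_names = FALSE)
  invisible(path)
}

#' Read microarray turnover probes
#'
#' TSV with header columns `chrom`, `start`, `end`, `rate` (0-based
#' half-open intervals; `rate` in turnover units, `NA` allowed for probes
#' without an estimate).
#'
#' @param path input file.
#' @return tibble of probes.
#' @export
read_turnover_probes <- function(path) {
  d <- readr::read_tsv(path, col_types = "ciid", progress = FALSE)
  need <- c("chrom", "start", "end", "rate")
  if (!all(need %in% names(d)))
    abort(paste0("probe file needs columns: ", paste(need, collapse = ", ")))
  if (any(d$end <= d$start)) abort("probe with end <= start")
  d
}

#' Read a promoter factor-occupancy matrix
#'
#' Wide TSV: first column `gene_id`, remaining columns one per factor.
#'
#' @param path input file.
#' @return tibble, genes in rows, factors in columns.
#' @export
read_occupancy_matrix <- function(path) {
  d <- readr::read_tsv(path, col_types = readr::cols(
    gene_id = readr::col_character(), .default = readr::col_double()),
    progress = FALSE)
  if (names(d)[1L] != "gene_id") abort("first column must be gene_id")
  d
}
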