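#' Per-base genome signal tracks
#'
#' A `genome_track` holds one numeric signal value per base per chromosome,
#' either stranded (separate Watson and Crick signal, e.g. NET-seq per-base
#' read counts) or unstranded (e.g. nucleosome occupancy, ChIP signal).
#' Missing data is `NA`, which is distinct from a measured zero; positions a
#' bedGraph leaves uncovered read as 0 (counts of zero), whereas positions
#' dropped during normalisation (H3 below the floor) or falling off a
#' chromosome end are `NA` and are skipped by every averaging step.
#'
#' @param watson,crick named lists of numeric vectors (one per chromosome)
#'   holding Watson-strand and Crick-strand signal.
#' @param values named list of numeric vectors for an unstranded track.
#' @param resolution base pairs per element; only 1 is currently used.
#' @return a `genome_track` object.
#' @examples
#' tr <- stranded_track(watson = list(chrI = c(0, 3, 0)),
#'                      crick  = list(chrI = c(1, 0, 0)))
#' track_chroms(tr)
#' @export
stranded_track <- function(watson, crick, resolution = 1L) {
  chroms <- union(names(watson), names(crick))
  sizes <- vapply(chroms, function(ch) {
    max(length(watson[[ch]]) %||% 0L, length(crick[[ch]]) %||% 0L)
  }, integer(1))
  pad <- function(sig) {
    out <- lapply(chroms, function(ch) {
      v <- sig[[ch]] %||% numeric(0)
      if (length(v) < sizes[[ch]]) v <- c(v, numeric(sizes[[ch]] - length(v)))
      as.numeric(v)
    })
    names(out) <- chroms
    out
  }
  structure(
    list(signal = list(watson = pad(watson), crick = pad(crick)),
         stranded = TRUE, resolution = as.integer(resolution)),
    class = "genome_track"
  )
}

#' @rdname stranded_track
#' @export
unstranded_track <- function(values, resolution = 1L) {
  structure(
    list(signal = list(both = lapply(values, as.numeric)),
         stranded = FALSE, resolution = as.integer(resolution)),
    class = "genome_track"
  )
}

#' @rdname stranded_track
#' @param x a `genome_track`.
#' @export
track_chroms <- function(x) names(x$signal[[1L]])

#' @rdname stranded_track
#' @export
track_total <- function(x) {
  sum(vapply(x$signal, function(sig) {
    sum(vapply(sig, function(v) sum(v, na.rm = TRUE), numeric(1)))
  }, numeric(1)))
}

#' @export
print.genome_track <- function(x, ...) {
  sizes <- vapply(x$signal[[1L]], length, integer(1))
  cat(sprintf("<genome_track: %s, %d chromosome(s), %s bp, total signal %.4g>\n",
              if (x$stranded) "stranded" else "unstranded",
              length(sizes), format(sum(sizes), big.mark = ","),
              track_total(x)))
  invisible(x)
}

is_genome_track <- function(x) inherits(x, "genome_track")

#' Read a bedGraph file into per-base vectors
#'
#' Intervals are 0-based half-open; uncovered positions carry 0. Overlapping
#' intervals and negative coordinates are rejected.
#'
#' @param path bedGraph file.
#' @param chrom_sizes optional named integer vector; chromosomes absent from
#'   the file are created as all-zero, and file intervals must fit inside.
#'   When omitted, each chromosome's size is the largest end seen.
#' @return named list of numeric vectors, one per chromosome.
#' @export
read_bedgraph <- function(path, chrom_sizes = NULL) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  gr <- rtracklayer::import(path, format = "bedGraph")
  chrom <- as.character(GenomicRanges::seqnames(gr))
  start0 <- GenomicRanges::start(gr) - 1L
  end0 <- GenomicRanges::end(gr)
  score <- as.numeric(S4Vectors::mcols(gr)$score)
  if (length(start0) && min(start0) < 0L)
    abort(paste0("negative coordinates in ", path))
  chroms <- union(names(chrom_sizes), unique(chrom))
  out <- vector("list", length(chroms))
  names(out) <- chroms
  for (ch in chroms) {
    i <- which(chrom == ch)
    size <- chrom_sizes[[ch]] %||% (if (length(i)) max(end0[i]) else 0L)
    v <- numeric(size)
    if (length(i)) {
      o <- i[order(start0[i])]
      if (any(end0[o][-length(o)] > start0[o][-1L]))
        abort(sprintf("overlapping bedGraph intervals on %s in %s", ch, path))
      if (max(end0[o]) > size)
        abort(sprintf("interval beyond declared size of %s in %s", ch, path))
      for (j in o) if (end0[j] > start0[j]) v[(start0[j] + 1L):end0[j]] <- score[j]
    }
    out[[ch]] <- v
  }
  out
}

#' Write per-base signal as bedGraph
#'
#' Adjacent equal values are run-length merged; zeros and `NA` positions are
#' left uncovered; values are written with 6 significant digits.
#'
#' @param values named list of per-base numeric vectors (one per chromosome).
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_bedgraph <- function(values, path) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  for (ch in names(values)) {
    v <- signif(values[[ch]], 6)
    r <- rle(ifelse(is.na(v), 0, v))
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths
    keep <- r$values != 0
    if (any(keep)) {
      writeLines(sprintf("%s\t%d\t%d\t%.6g", ch, starts[keep], ends[keep],
                         r$values[keep]), con)
    }
  }
  invisible(path)
}

#' Read strand-specific signal from a Watson/Crick bedGraph pair
#'
#' @param path_watson,path_crick bedGraph files holding the + (Watson) and
#'   \eqn{-} (Crick) strand signal.
#' @inheritParams read_bedgraph
#' @return a stranded [genome_track][stranded_track].
#' @export
read_stranded_signal <- function(path_watson, path_crick, chrom_sizes = NULL) {
  w <- read_bedgraph(path_watson, chrom_sizes)
  c0 <- read_bedgraph(path_crick, chrom_sizes)
  stranded_track(w, c0)
}

#' @rdname read_stranded_signal
#' @param path a single bedGraph file with unstranded signal.
#' @export
read_unstranded_signal <- function(path, chrom_sizes = NULL) {
  unstranded_track(read_bedgraph(path, chrom_sizes))
}

#' Write a track to bedGraph file(s)
#'
#' Stranded tracks produce `<stem>_watson.bedGraph` / `<stem>_crick.bedGraph`;
#' unstranded tracks a single `<stem>.bedGraph`.
#'
#' @param track a `genome_track`.
#' @param stem output path stem (no extension).
#' @return character vector of files written, invisibly.
#' @export
write_track <- function(track, stem) {
  stopifnot(is_genome_track(track))
  if (track$stranded) {
    paths <- paste0(stem, c("_watson", "_crick"), ".bedGraph")
    write_bedgraph(track$signal$watson, paths[1L])
    write_bedgraph(track$signal$crick, paths[2L])
  } else {
    paths <- paste0(stem, ".bedGraph")
    write_bedgraph(track$signal$both, paths)
  }
  invisible(paths)
}

# Workhorse window extraction: genomic signal around one TSS, returned in
# transcriptional orientation. rel positions are half-open [rel_start, rel_end).
window_values_at <- function(track, chrom, tss, strand, rel_start, rel_end,
                             strand_mode = c("sense", "antisense", "unstranded")) {
  strand_mode <- match.arg(strand_mode)
  if (rel_start >= rel_end) abort("rel_start must be < rel_end")
  if (!chrom %in% track_chroms(track))
    abort(sprintf("chromosome %s absent from track", chrom))
  if (!strand %in% c("+", "-")) abort(sprintf("unknown strand '%s'", strand))
  rel <- rel_start:(rel_end - 1L)
  pos <- if (strand == "+") tss + rel else tss - rel   # 0-based genomic
  if (track$stranded) {
    sig <- switch(strand_mode,
      unstranded = NULL,
      sense = if (strand == "+") track$signal$watson else track$signal$crick,
      antisense = if (strand == "+") track$signal$crick else track$signal$watson
    )
    if (is.null(sig)) {
      v <- lookup_positions(track$signal$watson[[chrom]], pos) +
        lookup_positions(track$signal$crick[[chrom]], pos)
    } else {
      v <- lookup_positions(sig[[chrom]], pos)
    }
  } else {
    if (strand_mode != "unstranded")
      abort("sense/antisense extraction needs a stranded track")
    v <- lookup_positions(track$signal$both[[chrom]], pos)
  }
  v
}

lookup_positions <- function(vec, pos) {
  v <- rep(NA_real_, length(pos))
  ok <- pos >= 0L & pos < length(vec)
  v[ok] <- vec[pos[ok] + 1L]
  v
}

#' Extract TSS-relative signal for one gene
#'
#' Returns per-base values over the half-open relative window
#' `[rel_start, rel_end)` in transcriptional orientation: element 1 is the
#' most upstream requested position regardless of strand. For a `-` strand
#' gene the genomic interval is reflected about the TSS and reversed.
#' `strand_mode = "antisense"` reads the strand opposite the gene's coding
#' strand; `"unstranded"` reads an unstranded track (or the strand sum of a
#' stranded one). Positions off the chromosome end are `NA`.
#'
#' @param track a [genome_track][stranded_track].
#' @param gene a one-row data frame with columns `chrom`, `tss`, `strand`.
#' @param rel_start,rel_end window bounds in bp relative to the TSS.
#' @param strand_mode `"sense"`, `"antisense"` or `"unstranded"`.
#' @return numeric vector of length `rel_end - rel_start`.
#' @export
window_values <- function(track, gene, rel_start, rel_end,
                          strand_mode = c("sense", "antisense", "unstranded")) {
  stopifnot(is.data.frame(gene), nrow(gene) == 1L)
  window_values_at(track, gene$chrom, gene$tss, gene$strand,
                   rel_start, rel_end, strand_mode)
}

#' Normalise a histone-modification track to H3
#'
#' Histone-mark ChIP signal is divided position-wise by H3 signal so that
#' modification density is not confounded by nucleosome occupancy. Positions
#' where H3 falls below `floor` become `NA` (missing), never infinite.
#'
#' @param mod,h3 unstranded [genome_track][stranded_track]s sharing
#'   chromosomes and resolution.
#' @param epsilon added to the denominator.
#' @param floor H3 values strictly below this are treated as unmeasurable.
#' @return an unstranded `genome_track` of ratios.
#' @export
normalize_to_h3 <- function(mod, h3, epsilon = 0, floor = 1e-6) {
  stopifnot(is_genome_track(mod), is_genome_track(h3))
  if (mod$resolution != h3$resolution) abort("track resolutions differ")
  if (mod$stranded || h3$stranded) abort("normalize_to_h3 expects unstranded tracks")
  chroms <- track_chroms(mod)
  if (!setequal(chroms, track_chroms(h3))) abort("tracks cover different chromosomes")
  vals <- lapply(setNames(chroms, chroms), function(ch) {
    m <- mod$signal$both[[ch]]
    h <- h3$signal$both[[ch]]
    if (length(m) != length(h)) abort(sprintf("length mismatch on %s", ch))
    r <- m / (h + epsilon)
    r[is.na(h) | h < floor] <- NA_real_
    r
  })
  unstranded_track(vals, resolution = mod$resolution)
}

#' Scale NET-seq libraries to a common total
#'
#' Each strain's track is multiplied by (mean library total) / (strain
#' total), so all totals agree afterwards while within-strain count ratios
#' are preserved exactly.
#'
#' @param tracks named list of [genome_track][stranded_track]s, one per strain.
#' @return list of scaled tracks with a `"scale_factors"` attribute.
#' @export
normalize_libraries <- function(tracks) {
  stopifnot(length(tracks) >= 1L, all(vapply(tracks, is_genome_track, logical(1))))
  totals <- vapply(tracks, track_total, numeric(1))
  if (any(totals == 0))
    abort(paste0("zero-total library: ",
                 paste(names(tracks)[totals == 0], collapse = ", ")))
  target <- mean(totals)
  scales <- target / totals
  out <- purrr::imap(tracks, function(tr, nm) {
    s <- scales[[nm]]
    tr$signal <- lapply(tr$signal, function(sig) lapply(sig, function(v) v * s))
    tr
  })
  attr(out, "scale_factors") <- scales
  out
}
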