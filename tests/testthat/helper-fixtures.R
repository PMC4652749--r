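# Small in-code fixture builders shared across test files.

toy_gene <- function(gene_id = "g1", chrom = "chrI", start = 1000L,
                     end = 2000L, strand = "+") {
  tibble::tibble(
    gene_id = gene_id, chrom = chrom, start = start, end = end,
    strand = strand, dubious = FALSE,
    tss = ifelse(strand == "+", start, end - 1L),
    tes = ifelse(strand == "+", end - 1L, start))
}

toy_genes <- function(starts, ends, strands, chrom = "chrI") {
  purrr::pmap(list(seq_along(starts), starts, ends, strands),
              function(i, s, e, st) {
                toy_gene(sprintf("g%02d", i), chrom, s, e, st)
              }) |> dplyr::bind_rows()
}

# A stranded track with given per-base vectors (defaults to one 5 kb chrom).
toy_stranded <- function(watson = NULL, crick = NULL, size = 5000L,
                         chrom = "chrI") {
  w <- watson %||% numeric(size)
  cr <- crick %||% numeric(size)
  stranded_track(stats::setNames(list(w), chrom),
                 stats::setNames(list(cr), chrom))
}

toy_unstranded <- function(values, chrom = "chrI") {
  unstranded_track(stats::setNames(list(values), chrom))
}

# Independent brute-force Wilcoxon two-sided p by full enumeration of all
# choose(n1+n2, n1) assignments of pooled ranks to sample a.
enumerate_wilcoxon_p <- function(a, b) {
  n1 <- length(a)
  r <- rank(c(a, b), ties.method = "average")
  w_obs <- sum(r[seq_len(n1)])
  combos <- utils::combn(length(r), n1)
  sums <- apply(combos, 2L, function(i) sum(r[i]))
  p_le <- mean(sums <= w_obs + 1e-9)
  p_ge <- mean(sums >= w_obs - 1e-9)
  min(1, 2 * min(p_le, p_ge))
}

# Write a minimal bedGraph and return the path.
write_tmp_bedgraph <- function(lines) {
  path <- withr::local_tempfile(fileext = ".bedGraph",
                                .local_envir = parent.frame())
  writeLines(lines, path)
  path
}
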