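test_that("BED6 genes map to 0-based coordinates with strand-aware TSS/TES", {
  path <- withr::local_tempfile(fileext = ".bed")
  writeLines(c("chrI\t999\t2000\tYAL001C\t0\t+",
               "chrI\t999\t2000\tg2\t0\t-"), path)
  g <- read_genes(path, "bed")
  expect_equal(g$start, c(999L, 999L))
  expect_equal(g$end, c(2000L, 2000L))
  expect_equal(g$tss, c(999L, 1999L))
  expect_equal(g$tes, c(1999L, 999L))
  expect_false(any(g$dubious))
})

test_that("malformed BED lines and unknown strands are rejected by line", {
  path <- withr::local_tempfile(fileext = ".bed")
  writeLines(c("chrI\t0\t100\ta\t0\t+", "chrI\t200\t300"), path)
  expect_error(read_genes(path, "bed"), "line 2")
  path2 <- withr::local_tempfile(fileext = ".bed")
  writeLines("chrI\t0\t100\ta\t0\t.", path2)
  expect_error(read_genes(path2, "bed"), "strand")
})

test_that("GFF3 1-based starts convert and attributes survive", {
  path <- withr::local_tempfile(fileext = ".gff3")
  writeLines(c(
    "##gff-version 3",
    paste0("chrI\tsgd\tgene\t1000\t2000\t.\t+\t.\t",
           "ID=YAL001C;dubious=false;tata=containing"),
    paste0("chrI\tsgd\tgene\t3000\t3500\t.\t-\t.\t",
           "ID=YAL002W;dubious=true;tata=less")), path)
  g <- read_genes(path, "gff3")
  expect_equal(g$start, c(999L, 2999L))      # 1-based inclusive -> 0-based
  expect_equal(g$end, c(2000L, 3500L))
  expect_equal(g$dubious, c(FALSE, TRUE))
  expect_equal(g$tata, c("containing", "less"))
  expect_equal(g$tss[2], 3499L)
})

test_that("bedGraph expansion honours half-open intervals", {
  p <- write_tmp_bedgraph("chrI\t0\t10\t3.0")
  v <- read_bedgraph(p, c(chrI = 15L))$chrI
  expect_equal(v[1:10], rep(3, 10))
  expect_equal(v[11], 0)

  p2 <- write_tmp_bedgraph(c("chrI\t0\t5\t1.0", "chrI\t5\t8\t2.0"))
  v2 <- read_bedgraph(p2)$chrI
  expect_equal(v2[6], 2)                     # position 5 belongs to 2nd record
  expect_equal(v2, c(rep(1, 5), rep(2, 3)))

  empty <- write_tmp_bedgraph(character(0))
  expect_equal(read_bedgraph(empty, c(chrI = 8L))$chrI, numeric(8))
})

test_that("overlapping intervals and negative coordinates error out", {
  p <- write_tmp_bedgraph(c("chrI\t0\t10\t1", "chrI\t5\t12\t2"))
  expect_error(read_bedgraph(p), "overlap")
  p2 <- write_tmp_bedgraph("chrI\t-5\t10\t1")
  expect_error(read_bedgraph(p2), "negative")
})

test_that("bedGraph round-trips exactly modulo run-length merging", {
  set.seed(42)
  for (rep in 1:5) {
    v <- sample(c(0, 0, 1.25, 2.5, 7), 60, replace = TRUE)
    path <- withr::local_tempfile(fileext = ".bedGraph")
    write_bedgraph(list(chrI = v), path)
    back <- read_bedgraph(path, c(chrI = 60L))$chrI
    expect_equal(back, v)
  }
})

test_that("window extraction follows the orientation convention", {
  # + gene, antisense = Crick over [tss, tss+300)
  cr <- numeric(5000); cr[1001:1300] <- 2       # genomic 1000..1299
  tr <- toy_stranded(crick = cr)
  gp <- toy_gene(strand = "+", start = 1000L, end = 2000L)
  expect_equal(sum(window_values(tr, gp, 0, 300, "antisense")), 600)
  expect_equal(window_values(tr, gp, 0, 300, "sense"), numeric(300))

  # - gene, tss = 2000: antisense reads Watson genomic (1700, 2000], reversed
  w <- numeric(5000); w[1702:2001] <- seq_len(300)   # genomic 1701..2000
  tr2 <- toy_stranded(watson = w)
  gm <- toy_gene(strand = "-", start = 500L, end = 2001L)
  v <- window_values(tr2, gm, 0, 300, "antisense")
  # oriented index i = genomic tss - i: first element genomic 2000 (=300)
  expect_equal(v, rev(seq_len(300)))

  # all-zero track
  expect_equal(window_values(toy_stranded(), gp, 0, 300, "antisense"),
               numeric(300))
})

test_that("positions off the chromosome end are missing, absent chrom errors", {
  tr <- toy_stranded(size = 1100L)
  g <- toy_gene(start = 1000L, end = 1090L)
  v <- window_values(tr, g, 0, 200, "sense")
  expect_true(all(is.na(v[101:200])))
  expect_false(anyNA(v[1:100]))
  g2 <- toy_gene(chrom = "chrX")
  expect_error(window_values(tr, g2, 0, 10, "sense"), "chrX")
})

test_that("minus-strand windows equal mirror-image plus-strand windows", {
  set.seed(7)
  size <- 400L
  for (rep in 1:20) {
    w <- rpois(size, 0.5); cr <- rpois(size, 0.5)
    tr <- toy_stranded(watson = w, crick = cr, size = size)
    # mirrored track: position p -> size-1-p, strands swapped
    tr_m <- toy_stranded(watson = rev(cr), crick = rev(w), size = size)
    tss <- sample(150:250, 1)
    gm <- toy_gene(strand = "-", start = 10L, end = tss + 1L)
    gp <- toy_gene(strand = "+", start = size - 1L - tss, end = size - 10L)
    for (mode in c("sense", "antisense")) {
      expect_equal(window_values(tr, gm, -50, 100, mode),
                   window_values(tr_m, gp, -50, 100, mode))
    }
  }
})

test_that("window sums match per-position brute force", {
  set.seed(11)
  cr <- rpois(3000, 0.2)
  tr <- toy_stranded(crick = cr, size = 3000L)
  g <- toy_gene(strand = "+", start = 1200L, end = 2400L)
  brute <- sum(vapply(0:299, function(r) cr[1200 + r + 1], numeric(1)))
  expect_equal(sum(window_values(tr, g, 0, 300, "antisense")), brute)
})

test_that("stranded library totals and scaling behave", {
  tr1 <- toy_stranded(watson = c(rep(1, 50), numeric(50)), size = 100L)
  tr2 <- toy_stranded(crick = c(rep(3, 50), numeric(50)), size = 100L)
  norm <- normalize_libraries(list(a = tr1, b = tr2))
  expect_equal(attr(norm, "scale_factors"), c(a = 2, b = 2 / 3))
  expect_equal(track_total(norm$a), track_total(norm$b))
  expect_equal(track_total(norm$a), 100)
  # internal ratios preserved
  expect_equal(norm$b$signal$crick$chrI[1] / norm$b$signal$crick$chrI[50], 1)
  expect_error(normalize_libraries(list(a = tr1, z = toy_stranded(size = 10L))),
               "zero-total")
})
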