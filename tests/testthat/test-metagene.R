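test_that("H3 normalisation divides element-wise and flags missing H3", {
  mod <- toy_unstranded(c(4, 9, 1, 0, 5))
  h3 <- toy_unstranded(c(2, 3, 0, 2, NA))
  r <- normalize_to_h3(mod, h3, epsilon = 0, floor = 1e-6)
  expect_equal(r$signal$both$chrI, c(2, 3, NA, 0, NA))
  set.seed(12)
  m2 <- abs(rnorm(10)) + 1; h2 <- abs(rnorm(10)) + 1
  r2 <- normalize_to_h3(toy_unstranded(m2), toy_unstranded(h2))
  expect_equal(r2$signal$both$chrI, m2 / h2)
  expect_error(normalize_to_h3(mod, toy_unstranded(1:3, chrom = "chrZ")),
               "chromosomes")
  h3r <- toy_unstranded(c(1, 1, 1, 1, 1)); h3r$resolution <- 10L
  expect_error(normalize_to_h3(mod, h3r), "resolution")
})

test_that("metagene of a constant track is flat; single bins average", {
  genes <- toy_genes(starts = c(1200L, 2600L), ends = c(2200L, 3600L),
                     strands = c("+", "-"))
  tr <- toy_unstranded(rep(3.5, 5000))
  mp <- metagene_profile(genes, tr, range = c(-200L, 400L), bin = 10L)
  expect_true(all(mp$value == 3.5))
  expect_equal(nrow(mp), 60L)

  v <- numeric(5000); v[1201:1210] <- 1:10       # rel 0..9 of gene at 1200
  g1 <- genes[1, ]
  mp1 <- metagene_profile(g1, toy_unstranded(v), range = c(0L, 10L), bin = 10L)
  expect_equal(mp1$value, 5.5)
})

test_that("opposite-strand genes with mirror signals contribute identically", {
  size <- 5000L
  shape <- dnorm(seq(-300, 499), 100, 80)
  vp <- numeric(size); vp[2001:2800] <- shape        # + gene, tss 2300
  # - gene, tss 2000: rel r is genomic 2000 - r, so rel [-300, 500) covers
  # genomic 1501..2300 (indices 1502..2301), mirrored
  vm <- numeric(size); vm[1502:2301] <- rev(shape)
  gp <- toy_gene("gp", start = 2300L, end = 3000L, strand = "+")
  gm <- toy_gene("gm", start = 1200L, end = 2001L, strand = "-")
  mp <- metagene_profile(gp, toy_unstranded(vp), range = c(-300L, 500L))
  mm <- metagene_profile(gm, toy_unstranded(vm), range = c(-300L, 500L))
  expect_equal(mp$value, mm$value)
})

test_that("metagene is linear in the track", {
  set.seed(13)
  genes <- toy_genes(starts = c(1500L, 3000L), ends = c(2500L, 4000L),
                     strands = c("+", "-"))
  t1 <- abs(rnorm(5000)); t2 <- abs(rnorm(5000))
  m1 <- metagene_profile(genes, toy_unstranded(t1), range = c(-100L, 200L))
  m2 <- metagene_profile(genes, toy_unstranded(t2), range = c(-100L, 200L))
  m12 <- metagene_profile(genes, toy_unstranded(2 * t1 + 3 * t2),
                          range = c(-100L, 200L))
  expect_equal(m12$value, 2 * m1$value + 3 * m2$value)
})

test_that("correlation profile recovers manufactured dependence", {
  # 40 genes whose bin signal equals their antisense count everywhere
  set.seed(14)
  n <- 40L
  starts <- seq(1000L, by = 3000L, length.out = n)
  genes <- toy_genes(starts = starts, ends = starts + 1000L,
                     strands = rep(c("+", "-"), n / 2))
  anti <- sample(1:200, n)
  sens <- sample(1:200, n)
  v <- numeric(max(starts) + 3000L)
  for (i in seq_len(n)) v[(starts[i] - 500):(starts[i] + 1500)] <- anti[i]
  tr <- toy_unstranded(v)
  counts <- tibble::tibble(gene_id = genes$gene_id, sense = sens,
                           antisense = anti)
  cp <- correlation_profile(genes, tr, counts, range = c(-100L, 200L))
  expect_true(all(cp$rho[cp$target == "antisense"] == 1))
  expect_true(all(abs(cp$rho[cp$target == "sense"]) < 0.5))
})

test_that("correlation profile of iid noise stays inside the null envelope", {
  set.seed(15)
  n <- 500L
  starts <- seq(500L, by = 250L, length.out = n)
  genes <- toy_genes(starts = starts, ends = starts + 200L,
                     strands = sample(c("+", "-"), n, replace = TRUE))
  tr <- toy_unstranded(rnorm(max(starts) + 1000L))
  counts <- tibble::tibble(gene_id = genes$gene_id,
                           sense = sample(1:1000, n),
                           antisense = sample(1:1000, n))
  cp <- correlation_profile(genes, tr, counts, range = c(-100L, 100L))
  expect_true(all(abs(cp$rho) < 0.12, na.rm = TRUE))
  expect_true(all(cp$n == n))
})

test_that("correlation profile matches the rank oracle on a 5-gene toy", {
  starts <- seq(1000L, by = 2000L, length.out = 5)
  genes <- toy_genes(starts = starts, ends = starts + 500L,
                     strands = rep("+", 5))
  vals <- c(3, 1, 4, 1, 5)
  v <- numeric(12000)
  for (i in 1:5) v[(starts[i] + 1):(starts[i] + 10)] <- vals[i]
  counts <- tibble::tibble(gene_id = genes$gene_id,
                           sense = c(9, 2, 6, 5, 3),
                           antisense = c(1, 8, 2, 7, 4))
  cp <- correlation_profile(genes, toy_unstranded(v), counts,
                            range = c(0L, 10L))
  expect_equal(cp$rho[cp$target == "sense"],
               cor(vals, counts$sense, method = "spearman"))
  expect_equal(cp$rho[cp$target == "antisense"],
               cor(vals, counts$antisense, method = "spearman"))
  # invariant under strictly monotone transform of the track
  cp2 <- correlation_profile(genes, toy_unstranded(exp(v)), counts,
                             range = c(0L, 10L))
  expect_equal(cp2$rho, cp$rho)
})

test_that("extremum group test locates the dip and contrasts groups", {
  set.seed(16)
  n <- 60L
  starts <- seq(1000L, by = 2000L, length.out = n)
  genes <- toy_genes(starts = starts, ends = starts + 800L,
                     strands = rep("+", n))
  ga <- genes$gene_id[1:30]; gb <- genes$gene_id[31:60]
  # dip at rel +100 for every gene; group A offset by +1
  base <- function(rel) 1 - 0.8 * exp(-((rel - 100)^2) / (2 * 30^2))
  v <- numeric(max(starts) + 3000L)
  for (i in seq_len(n)) {
    rel <- -300:799
    v[starts[i] + rel + 1] <- base(rel) + (i <= 30) + rnorm(1100, 0, 0.1)
  }
  tr <- toy_unstranded(v)
  res <- extremum_group_test(genes, tr, ga, gb, polarity = "min",
                             vicinity = c(-300L, 300L))
  expect_lte(abs(res$position - 100L), 20L)   # dip bin
  expect_lt(res$p_value, 1e-6)
  # identical groups: p = 1
  res2 <- extremum_group_test(genes, tr, ga, ga, polarity = "min")
  expect_equal(res2$p_value, 1)
})
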