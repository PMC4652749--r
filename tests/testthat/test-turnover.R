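test_that("body windows tile the transcribed region without overlap", {
  g <- toy_gene(start = 1000L, end = 1230L)     # length 230 -> 4 full windows
  set.seed(18)
  tr <- toy_unstranded(rnorm(5000))
  bt <- body_window_table(g, tr, toy_stranded(), width = 50L)
  expect_equal(nrow(bt), 4L)                    # partial 5th window dropped
  expect_equal(bt$rel_start, c(0L, 50L, 100L, 150L))
  # window means equal hand-computed slice means
  v <- tr$signal$both$chrI
  expect_equal(bt$mod[2], mean(v[(1000 + 50 + 1):(1000 + 100)]))
})

test_that("body window table matches hand values on a 2-gene toy", {
  gp <- toy_gene("gp", start = 1000L, end = 1100L, strand = "+")
  gm <- toy_gene("gm", start = 2000L, end = 2101L, strand = "-")  # tss 2100
  v <- numeric(5000)
  v[1001:1100] <- rep(c(2, 4), each = 50)       # gp windows: 2 then 4
  v[2052:2101] <- 6                             # gm oriented window 1
  v[2002:2051] <- 8                             # gm oriented window 2
  w <- numeric(5000); w[1001:1050] <- 1          # 50 sense reads gp window 1
  cr <- numeric(5000); cr[2052:2101] <- 1        # gm sense (crick), window 1
  bt <- body_window_table(dplyr::bind_rows(gp, gm), toy_unstranded(v),
                          toy_stranded(watson = w, crick = cr), width = 50L)
  expect_equal(bt$mod[bt$gene_id == "gp"], c(2, 4))
  expect_equal(bt$mod[bt$gene_id == "gm"], c(6, 8))
  expect_equal(bt$sense[bt$gene_id == "gp"], c(50, 0))
  expect_equal(bt$sense[bt$gene_id == "gm"], c(50, 0))
})

test_that("pooled body correlation recovers manufactured dependence", {
  set.seed(19)
  n <- 20L
  starts <- seq(1000L, by = 3000L, length.out = n)
  genes <- toy_genes(starts = starts, ends = starts + 2500L,
                     strands = rep("+", n))
  anti <- sample(0:50, n, replace = TRUE)
  v <- numeric(max(starts) + 4000L)
  cr <- numeric(max(starts) + 4000L)
  for (i in seq_len(n)) {
    # mod level and per-window antisense count are both proportional to
    # anti[i], so their pooled ranks coincide exactly
    v[(starts[i] + 1):(starts[i] + 2500)] <- anti[i]
    cr[(starts[i] + 1):(starts[i] + 2500)] <- anti[i] / 2500
  }
  bt <- body_window_table(genes, toy_unstranded(v),
                          toy_stranded(crick = cr))
  bc <- body_window_correlation(bt)
  expect_equal(bc$rho[bc$target == "antisense"], 1)

  # independent noise: 1000 windows stay inside the envelope
  v2 <- rnorm(length(v))
  bt2 <- body_window_table(genes, toy_unstranded(v2),
                           toy_stranded(watson = abs(rnorm(length(v))),
                                        crick = abs(rnorm(length(v)))))
  expect_gte(nrow(bt2), 1000L)
  bc2 <- body_window_correlation(bt2)
  expect_true(all(abs(bc2$rho) < 0.07))
})

test_that("body correlation matches the rank oracle on a tiny table", {
  bt <- tibble::tibble(gene_id = rep(c("a", "b"), each = 2),
                       window = c(1, 2, 1, 2), rel_start = c(0, 50, 0, 50),
                       mod = c(1.5, 0.2, 3.1, 2.2),
                       sense = c(10, 3, 8, 1), antisense = c(0, 5, 2, 9))
  bc <- body_window_correlation(bt)
  expect_equal(bc$rho[bc$target == "sense"],
               cor(bt$mod, bt$sense, method = "spearman"))
  expect_equal(bc$rho[bc$target == "antisense"],
               cor(bt$mod, bt$antisense, method = "spearman"))
  # gene order invariance
  bc2 <- body_window_correlation(bt[c(3, 4, 1, 2), ])
  expect_equal(bc2$rho, bc$rho)
})

test_that("region turnover takes the max over >=1 bp overlapping probes", {
  g <- toy_gene(start = 1000L, end = 3000L)
  map <- nucleosome_map(gene_id = rep("g1", 5), index = c(-1L, 1L:4L),
                        chrom = "chrI",
                        start = c(800L, 1000L, 1165L, 1330L, 1495L),
                        end = c(947L, 1147L, 1312L, 1477L, 1642L))
  probes <- tibble::tibble(chrom = "chrI",
                           start = c(700L, 900L, 1200L, 1642L, 300L),
                           end = c(800L, 1100L, 1500L, 1800L, 500L),
                           rate = c(0.7, 0.2, 0.9, 0.5, 2.0))
  # probe 1 ends exactly at region start (800): zero overlap, excluded;
  # probe 4 starts exactly at region end (1642): excluded; probe 5 far away
  res <- region_turnover(probes, map, g)
  expect_equal(res$rate, 0.9)
  expect_equal(res$n_probes, 2L)
  # no overlapping probe: missing, logged
  res2 <- region_turnover(probes[5, ], map, g)
  expect_true(is.na(res2$rate))
  expect_equal(attr(res2, "no_probe"), "g1")
})

test_that("region turnover equals brute force and is probe-monotone", {
  set.seed(20)
  g <- toy_gene(start = 2000L, end = 5000L)
  map <- nucleosome_map(gene_id = rep("g1", 5), index = c(-1L, 1L:4L),
                        chrom = "chrI",
                        start = 1800L + (0:4) * 165L,
                        end = 1800L + (0:4) * 165L + 147L)
  region <- c(min(map$start), max(map$end))
  for (rep in 1:10) {
    k <- sample(3:12, 1)
    st <- sample(1000:3000, k)
    probes <- tibble::tibble(chrom = "chrI", start = st,
                             end = st + sample(50:400, k, replace = TRUE),
                             rate = round(runif(k), 3))
    qual <- probes$start < region[2] & probes$end > region[1]
    res <- region_turnover(probes, map, g)
    if (any(qual)) {
      expect_equal(res$rate, max(probes$rate[qual]))
      expect_equal(res$n_probes, sum(qual))
    } else {
      expect_true(is.na(res$rate))
    }
    # adding a probe never decreases the rate
    extra <- tibble::tibble(chrom = "chrI", start = region[1],
                            end = region[1] + 10L, rate = 0)
    res2 <- region_turnover(dplyr::bind_rows(probes, extra), map, g)
    expect_gte(res2$rate, ifelse(is.na(res$rate), 0, res$rate))
  }
})

test_that("per-class turnover distributions summarise and test correctly", {
  set.seed(21)
  # identical class distributions: contrast p near 1
  nuc <- tibble::tibble(gene_id = rep(sprintf("g%02d", 1:40), each = 2),
                        index = rep(c(-1L, 1L), 40),
                        rate = rep(rep(c(1, 2, 3, 4), 10), each = 2),
                        n_probes = 1L)
  classes <- tibble::tibble(gene_id = sprintf("g%02d", 1:40),
                            class = rep(rep(c(1L, 5L), each = 4), 5))
  td <- turnover_class_distributions(nuc, classes)
  expect_true(all(td$tests$p_value > 0.5))
  # 3-gene toy quartiles equal hand values
  nuc2 <- tibble::tibble(gene_id = c("a", "b", "c"), index = 1L,
                         rate = c(1, 2, 4), n_probes = 1L)
  cl2 <- tibble::tibble(gene_id = c("a", "b", "c"), class = c(1L, 1L, 2L))
  td2 <- turnover_class_distributions(nuc2, cl2)
  s <- td2$summary
  expect_equal(s$median[s$class == 1], 1.5)
  expect_equal(s$q1[s$class == 1], 1.25)
  expect_equal(s$q3[s$class == 1], 1.75)
})

test_that("probe-wise turnover/modification correlation hits the extremes", {
  probes <- tibble::tibble(chrom = "chrI", start = (0:5) * 100L,
                           end = (0:5) * 100L + 100L,
                           rate = c(0.1, 0.3, 0.5, 0.6, 0.8, 0.9))
  v <- rep(probes$rate, each = 100)
  expect_equal(turnover_modification_correlation(probes, toy_unstranded(v))$rho, 1)
  v2 <- rep(rev(probes$rate), each = 100)
  expect_equal(turnover_modification_correlation(probes,
                                                 toy_unstranded(v2))$rho, -1)
  # 6-probe fixture vs independent oracle
  set.seed(22)
  mod <- runif(6)
  v3 <- rep(mod, each = 100)
  expect_equal(turnover_modification_correlation(probes,
                                                 toy_unstranded(v3))$rho,
               cor(mod, probes$rate, method = "spearman"))
})
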