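#' Spearman rank correlation
#'
#' Computes the Spearman coefficient as the Pearson correlation of
#' tie-averaged rank vectors, after pairwise removal of missing values.
#' When either margin is constant the coefficient is undefined and returned
#' flagged rather than as an error, because constant windows occur routinely
#' in genome-wide profiling (e.g. a mark absent from every gene at one
#' position).
#'
#' @param x,y numeric vectors of equal length.
#' @return one-row tibble: `rho`, `n` (pairs used), `defined` (logical).
#' @examples
#' spearman_cor(1:4, c(10, 20, 30, 40))$rho  # 1
#' @export
spearman_cor <- function(x, y) {
  if (length(x) != length(y)) abort("x and y must have equal length")
  ok <- !(is.na(x) | is.na(y))
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3L) abort("need >= 3 complete pairs")
  rx <- rank(x, ties.method = "average")
  ry <- rank(y, ties.method = "average")
  dx <- rx - mean(rx); dy <- ry - mean(ry)
  sx <- sum(dx^2); sy <- sum(dy^2)
  if (sx == 0 || sy == 0)
    return(tibble(rho = NA_real_, n = n, defined = FALSE))
  tibble(rho = sum(dx * dy) / sqrt(sx * sy), n = n, defined = TRUE)
}

#' Two-sided Wilcoxon rank-sum test
#'
#' The statistic is the Mann-Whitney U for sample `a`. In exact mode the
#' two-sided p-value is computed from the exact conditional distribution of
#' the rank sum given the observed (possibly tied) pooled ranks, by counting
#' subset rank sums with a dynamic program -- equivalent to enumerating all
#' `choose(n1 + n2, n1)` assignments. In approximate mode the normal
#' approximation with the standard tie variance correction and (by default)
#' a 0.5 continuity correction is used. `mode = "auto"` picks exact when
#' both samples are at most `exact_threshold`.
#'
#' @param a,b numeric vectors (non-empty; `NA` dropped).
#' @param mode `"auto"`, `"exact"` or `"approx"`.
#' @param exact_threshold largest per-sample size for automatic exact mode.
#' @param continuity apply the continuity correction in approximate mode.
#' @return one-row tibble: `statistic` (U), `p_value`, `method`, `n1`, `n2`.
#' @examples
#' wilcoxon_rank_sum(1:3, 4:6, mode = "exact")$p_value  # 0.1
#' @export
wilcoxon_rank_sum <- function(a, b, mode = c("auto", "exact", "approx"),
                              exact_threshold = 12L, continuity = TRUE) {
  mode <- match.arg(mode)
  a <- a[!is.na(a)]; b <- b[!is.na(b)]
  n1 <- length(a); n2 <- length(b)
  if (n1 == 0L || n2 == 0L) abort("both samples must be non-empty")
  if (mode == "auto")
    mode <- if (max(n1, n2) <= exact_threshold) "exact" else "approx"
  r <- rank(c(a, b), ties.method = "average")
  w <- sum(r[seq_len(n1)])                      # rank sum of sample a
  u <- w - n1 * (n1 + 1) / 2
  if (length(unique(c(a, b))) == 1L) {          # everything tied
    return(tibble(statistic = u, p_value = 1, method = mode,
                  n1 = n1, n2 = n2))
  }
  if (mode == "exact") {
    p <- exact_ranksum_p(r, n1, w)
  } else {
    n <- n1 + n2
    mu <- n1 * (n + 1) / 2
    ties <- table(r)
    sigma2 <- n1 * n2 / 12 * ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
    if (sigma2 <= 0) {
      p <- 1
    } else {
      d <- w - mu
      cc <- if (continuity) sign(d) * 0.5 else 0
      z <- (d - cc) / sqrt(sigma2)
      p <- min(1, 2 * pnorm(-abs(z)))
    }
  }
  tibble(statistic = u, p_value = p, method = mode, n1 = n1, n2 = n2)
}

# Exact two-sided p for the rank sum, conditional on the observed pooled
# ranks. Ranks are doubled so tie-averaged halves become integers; a DP
# counts, for every achievable sum, the number of size-n1 subsets attaining
# it. Counts stay well inside double precision for the sizes exact mode is
# used at.
exact_ranksum_p <- function(r, n1, w) {
  ir <- as.integer(round(2 * r))
  total <- choose(length(r), n1)
  smax <- sum(sort(ir, decreasing = TRUE)[seq_len(n1)])
  # f[j+1, s+1] = number of j-subsets with doubled-rank sum s
  f <- matrix(0, nrow = n1 + 1L, ncol = smax + 1L)
  f[1L, 1L] <- 1
  maxj <- 0L
  for (x in ir) {
    for (j in seq(min(maxj, n1 - 1L), 0L)) {
      src <- f[j + 1L, ]
      nz <- which(src > 0)
      if (length(nz)) {
        dest <- nz + x
        keep <- dest <= smax + 1L
        f[j + 2L, dest[keep]] <- f[j + 2L, dest[keep]] + src[nz[keep]]
      }
    }
    maxj <- min(n1, maxj + 1L)
  }
  counts <- f[n1 + 1L, ]
  sums <- (seq_along(counts) - 1L) / 2          # back to rank-sum scale
  p_le <- sum(counts[sums <= w + 1e-9]) / total
  p_ge <- sum(counts[sums >= w - 1e-9]) / total
  min(1, 2 * min(p_le, p_ge))
}
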