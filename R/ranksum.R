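#' Two-sided Mann-Whitney rank-sum test (exact or tie-corrected normal)
#'
#' The rarity screen for CNVs is a rank-sum comparison of per-window copy
#' ratios. For small samples (n1 + n2 <= `exact_max`) the exact two-sided
#' p-value is computed from the full permutation distribution of the
#' rank-sum (midranks under ties) via a dynamic-programming convolution;
#' larger samples use the normal approximation with tie-corrected variance
#' and continuity correction. The two-sided p is `min(1, 2 * min(P(W <= w),
#' P(W >= w)))`, matching the conventional definition.
#'
#' @param x,y numeric samples
#' @param exact_max largest combined sample size for the exact path
#' @return list with `statistic` (U for sample x), `p`, `method`
#' @export
ranksum_test <- function(x, y, exact_max = 40) {
  n1 <- length(x); n2 <- length(y); N <- n1 + n2
  if (n1 == 0 || n2 == 0) stop_input("empty sample in rank-sum test")
  r <- rank(c(x, y))
  W <- sum(r[seq_len(n1)])
  U <- W - n1 * (n1 + 1) / 2
  if (N <= exact_max) {
    p <- ranksum_exact_p(r, n1, W)
    return(list(statistic = U, p = p, method = "exact"))
  }
  ties <- table(r)
  tiecorr <- sum(ties^3 - ties) / (N * (N - 1))
  mu <- n1 * n2 / 2
  sigma <- sqrt(n1 * n2 / 12 * ((N + 1) - tiecorr))
  z <- (U - mu - sign(U - mu) * 0.5) / sigma
  list(statistic = U, p = min(1, 2 * stats::pnorm(-abs(z))),
       method = "normal")
}

# exact permutation distribution of the rank-sum via DP over doubled
# midranks (so ties stay integer); returns the two-sided p
ranksum_exact_p <- function(r, n1, W) {
  v <- sort(round(2 * r))           # doubled midranks, integers
  N <- length(v); smax <- sum(v)
  # f[k+1, s+1] = number of k-subsets with doubled-rank sum s
  f <- matrix(0, nrow = n1 + 1, ncol = smax + 1)
  f[1, 1] <- 1
  for (val in v) {
    for (k in min(n1, N):1) {
      idx <- which(f[k, ] > 0)
      if (length(idx)) {
        tgt <- idx + val
        f[k + 1, tgt] <- f[k + 1, tgt] + f[k, idx]
      }
    }
  }
  dist <- f[n1 + 1, ]
  tot <- sum(dist)
  w2 <- round(2 * W)
  sums <- seq_len(smax + 1) - 1
  pl <- sum(dist[sums <= w2]) / tot
  pu <- sum(dist[sums >= w2]) / tot
  min(1, 2 * min(pl, pu))
}
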