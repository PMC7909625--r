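# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: segmentation is checked by exhaustive enumeration
# of rule-satisfying partitions, regressions by direct normal-equations
# solves.

# Enumerate every partition of the reference years that satisfies the cohort
# construction rules: within each interval every year-to-year extension is
# permitted, and each non-final interval cannot be extended by one more year.
# Returns a list of start-index vectors (expected: exactly one).
oracle_segment <- function(ref, band_low = 0.05, band_high = 0.06,
                           jump = 0.02) {
  p <- ref$prop_early
  n <- ref$n
  K <- nrow(ref)
  ext_ok <- function(s, i) {
    # may a cohort opened at year s extend from year i to i + 1?
    if (abs(p[i + 1] - p[i]) > jump) return(FALSE)
    governed <- p[s] >= band_low && p[s] <= band_high
    if (governed) {
      pooled <- sum(p[s:(i + 1)] * n[s:(i + 1)]) / sum(n[s:(i + 1)])
      if (pooled < band_low || pooled > band_high) return(FALSE)
    }
    TRUE
  }
  valid <- function(starts) {
    ends <- c(starts[-1] - 1L, K)
    for (ci in seq_along(starts)) {
      s <- starts[ci]
      e <- ends[ci]
      if (e > s) {
        for (i in s:(e - 1)) if (!ext_ok(s, i)) return(FALSE)
      }
      if (ci < length(starts) && ext_ok(s, e)) return(FALSE)
    }
    TRUE
  }
  found <- list()
  if (K == 1) return(list(1L))
  for (mask in 0:(2^(K - 1) - 1)) {
    starts <- c(1L, which(bitwAnd(mask, 2^(0:(K - 2))) > 0) + 1L)
    if (valid(starts)) found[[length(found) + 1]] <- starts
  }
  found
}

random_reference <- function(k, start_year = 1950L) {
  # mix of in-band years, drifting years and abrupt jumps
  p <- numeric(k)
  p[1] <- sample(c(stats::runif(1, 0.04, 0.07), stats::runif(1, 0.1, 0.4)), 1)
  for (i in 2:k) {
    step <- sample(c(stats::rnorm(1, 0, 0.006), stats::rnorm(1, 0, 0.08)), 1,
                   prob = c(0.8, 0.2))
    p[i] <- min(max(p[i - 1] + step, 0.005), 0.6)
  }
  tibble::tibble(
    birth_year = seq(start_year, length.out = k),
    mean_aam = stats::runif(k, 12, 17),
    sd_aam = stats::runif(k, 1, 2),
    prop_early = p,
    n = sample(50:500, k, replace = TRUE)
  )
}

# direct normal-equations OLS: coefficients and SEs
brute_ols <- function(y, X) {
  xtx_inv <- solve(crossprod(X))
  beta <- drop(xtx_inv %*% crossprod(X, y))
  res <- y - drop(X %*% beta)
  s2 <- sum(res^2) / (length(y) - ncol(X))
  list(coef = beta, se = sqrt(diag(xtx_inv) * s2),
       rss = sum(res^2), r2 = 1 - sum(res^2) / sum((y - mean(y))^2))
}

# summary-level generator: true exposure betas bx, observed with noise seX;
# outcome betas centred on beta * bx (+ per-SNP pleiotropy alpha), noise seY
make_summaries <- function(bx, beta, seX, seY, alpha = 0) {
  k <- length(bx)
  tibble::tibble(
    snp = sprintf("rs%03d", seq_len(k)),
    beta_exposure = bx + stats::rnorm(k, 0, seX),
    se_exposure = rep(seX, length.out = k),
    beta_outcome = beta * bx + alpha + stats::rnorm(k, 0, seY),
    se_outcome = rep(seY, length.out = k)
  )
}
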