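summ <- function(bx, by, seX = 0.05, seY = 0.1) {
  tibble::tibble(
    snp = sprintf("rs%03d", seq_along(bx)),
    beta_exposure = bx, se_exposure = rep(seX, length.out = length(bx)),
    beta_outcome = by, se_outcome = rep(seY, length.out = length(bx))
  )
}

test_that("Wald ratio arithmetic, invariance and errors", {
  s <- summ(0.5, 0.1)
  wr <- wald_ratio(s)
  expect_equal(wr$estimate, 0.2)
  expect_equal(wr$std.error, 0.1 / 0.5)
  expect_equal(wald_ratio(summ(0.5, 0))$estimate, 0)
  expect_equal(wald_ratio(summ(0.5, 0))$std.error, 0.1 / 0.5)
  # joint sign flip leaves the ratio unchanged
  expect_equal(wald_ratio(summ(-0.5, -0.1))$estimate, 0.2)
  expect_error(wald_ratio(summ(0, 0.1)), "zero")
})

test_that("IVW matches the hand-computed weighted mean and brute force", {
  s <- summ(c(0.5, 0.25), c(0.1, 0.05), seY = 0.1)
  fit <- mr_ivw(s)
  # weights 25 and 6.25; beta = 0.2; se = sqrt(1/31.25)
  expect_equal(fit$estimates$estimate, 0.2, tolerance = 1e-12)
  expect_equal(fit$estimates$std.error, sqrt(1 / 31.25), tolerance = 1e-12)
  expect_equal(fit$estimates$std.error, 0.1788854, tolerance = 1e-6)
  # identical ratios give that ratio under any weighting
  s2 <- summ(c(0.5, 0.2, 0.9), c(0.1, 0.04, 0.18), seY = c(0.1, 0.3, 0.05))
  expect_equal(mr_ivw(s2)$estimates$estimate, 0.2, tolerance = 1e-12)
  expect_error(mr_ivw(summ(0.5, 0.1)), "at least 2")
})

test_that("IVW equals the precision-weighted mean of Wald ratios", {
  set.seed(89)
  s <- summ(runif(10, 0.1, 0.5), rnorm(10, 0, 0.1),
            seY = runif(10, 0.05, 0.2))
  wr <- wald_ratio(s)
  w <- 1 / wr$std.error^2
  expect_equal(mr_ivw(s)$estimates$estimate,
               sum(w * wr$estimate) / sum(w), tolerance = 1e-12)
})

test_that("Cochran's Q matches the two-SNP hand computation and extremes", {
  s <- summ(c(1, 1), c(0.1, 0.3), seY = 0.1)
  beta_ivw <- mr_ivw(s)$estimates$estimate
  expect_equal(beta_ivw, 0.2, tolerance = 1e-12)
  q <- cochran_q(s, beta_ivw)
  expect_equal(q$Q, 2.0, tolerance = 1e-12)
  expect_equal(q$df, 1L)
  expect_equal(q$p, stats::pchisq(2, 1, lower.tail = FALSE), tolerance = 1e-12)
  # homogeneity: identical ratios give Q = 0, p = 1
  s0 <- summ(c(0.5, 0.25), c(0.15, 0.075))
  q0 <- cochran_q(s0, 0.3)
  expect_equal(q0$Q, 0)
  expect_equal(q0$p, 1)
})

test_that("weighted median interpolation matches hand computations", {
  # equal weights, ratios 0.1/0.2/0.3: cumulative hits 0.5 at the middle
  s <- summ(c(1, 1, 1), c(0.1, 0.2, 0.3), seY = 0.1)
  expect_equal(mr_weighted_median(s, n_boot = 0)$estimates$estimate, 0.2,
               tolerance = 1e-12)
  # all ratios equal c -> c regardless of weights
  s2 <- summ(c(0.2, 0.5, 0.8), c(0.2, 0.5, 0.8) * 0.7,
             seY = c(0.1, 0.2, 0.05))
  expect_equal(mr_weighted_median(s2, n_boot = 0)$estimates$estimate, 0.7,
               tolerance = 1e-12)
  # asymmetric weights: hand interpolation
  r <- c(0.1, 0.2, 0.4)
  w <- c(1, 2, 1)
  sw <- summ(c(1, 1, 1), r, seY = 1 / sqrt(w))
  sc <- cumsum(w / 4) - w / 8           # 0.125, 0.5, 0.875
  expect_equal(mr_weighted_median(sw, n_boot = 0)$estimates$estimate, 0.2,
               tolerance = 1e-12)
  expect_error(mr_weighted_median(summ(c(1, 1), c(0.1, 0.2))), "at least 3")
})

test_that("weighted median bootstrap SE is seeded and reproducible", {
  set.seed(97)
  s <- summ(runif(10, 0.2, 0.5), rnorm(10, 0.1, 0.05))
  a <- mr_weighted_median(s, n_boot = 200, seed = 5)
  b <- mr_weighted_median(s, n_boot = 200, seed = 5)
  expect_equal(a$estimates, b$estimates)
  expect_gt(a$estimates$std.error, 0)
})

test_that("MR-Egger recovers exact lines and flips orientation", {
  # three collinear points through the origin: intercept 0
  s0 <- summ(c(0.2, 0.5, 0.8), c(0.2, 0.5, 0.8) * 0.4)
  e0 <- mr_egger(s0)$estimates
  expect_equal(e0$estimate[e0$term == "slope"], 0.4, tolerance = 1e-10)
  expect_equal(e0$estimate[e0$term == "intercept"], 0, tolerance = 1e-10)
  # exact line through (0.25, 0.05) and (0.5, 0.15): slope 0.4, intercept -0.05
  s1 <- summ(c(0.25, 0.5, 0.75), c(0.05, 0.15, 0.25))
  e1 <- mr_egger(s1)$estimates
  expect_equal(e1$estimate[e1$term == "slope"], 0.4, tolerance = 1e-10)
  expect_equal(e1$estimate[e1$term == "intercept"], -0.05, tolerance = 1e-10)
  # negative exposure betas are flipped jointly: same slope, mirrored intercept
  s2 <- summ(-c(0.25, 0.5, 0.75), -c(0.05, 0.15, 0.25))
  e2 <- mr_egger(s2)$estimates
  expect_equal(e2$estimate[e2$term == "slope"], 0.4, tolerance = 1e-10)
  expect_equal(e2$estimate[e2$term == "intercept"], -0.05, tolerance = 1e-10)
  expect_error(mr_egger(summ(c(0.3, 0.3, 0.3), c(1, 2, 3))), "spread")
  expect_error(mr_egger(summ(c(0.2, 0.3), c(1, 2))), "at least 3")
})

test_that("MR-Egger matches a brute-force weighted regression", {
  set.seed(101)
  s <- summ(runif(8, 0.1, 0.6), rnorm(8, 0.1, 0.1),
            seY = runif(8, 0.05, 0.3))
  w <- 1 / s$se_outcome^2
  X <- cbind(1, s$beta_exposure)
  wls <- solve(crossprod(X * sqrt(w)), crossprod(X * sqrt(w),
                                                 s$beta_outcome * sqrt(w)))
  e <- mr_egger(s)$estimates
  expect_equal(e$estimate[e$term == "intercept"], wls[1], tolerance = 1e-8)
  expect_equal(e$estimate[e$term == "slope"], wls[2], tolerance = 1e-8)
})

test_that("Egger intercept tracks directional but not balanced pleiotropy", {
  set.seed(103)
  res <- purrr::map_dfr(1:100, function(i) {
    bx <- seq(0.1, 0.5, length.out = 14)
    s_dir <- make_summaries(bx, beta = -0.5, seX = 0.01, seY = 0.05,
                            alpha = 0.05)
    s_bal <- make_summaries(bx, beta = -0.5, seX = 0.01, seY = 0.05,
                            alpha = sample(c(-0.05, 0.05), 14, replace = TRUE))
    tibble::tibble(
      dir = mr_egger(s_dir)$estimates$estimate[2],
      bal = mr_egger(s_bal)$estimates$estimate[2]
    )
  })
  # 3 Monte-Carlo SEs of the 100-rep mean plus a dilution allowance
  expect_lt(abs(mean(res$dir) - 0.05), 0.012)
  expect_lt(abs(mean(res$bal)), 0.02)
})

test_that("leave-one-out bookkeeping and heterogeneity localisation", {
  s <- summ(rep(0.5, 5), rep(0.1, 5))
  loo <- leave_one_out(s)
  expect_equal(nrow(loo), 5)
  expect_equal(loo$estimate, rep(0.2, 5), tolerance = 1e-12)
  # one aberrant SNP: its exclusion row has the smallest Q
  s$beta_outcome[3] <- 0.4
  loo2 <- leave_one_out(s)
  expect_equal(which.min(loo2$Q), 3)
  expect_lt(loo2$Q[3], 1e-10)
})

test_that("MR-PRESSO flags an injected outlier and not homogeneous input", {
  s <- summ(rep(0.5, 6), rep(0.1, 6))
  fit0 <- mr_presso(s, n_sim = 500, seed = 7)
  expect_false(any(fit0$outliers$outlier))
  expect_equal(fit0$estimates$estimate[1], fit0$estimates$estimate[2])
  expect_true(is.na(fit0$distortion_p))

  set.seed(107)
  s1 <- make_summaries(seq(0.2, 0.6, length.out = 10), beta = 0.3,
                       seX = 0.01, seY = 0.05)
  s1$beta_outcome[4] <- s1$beta_outcome[4] + 10 * 0.05
  fit1 <- mr_presso(s1, n_sim = 1000, seed = 11)
  expect_true(fit1$outliers$outlier[4])
  expect_lt(fit1$global_p, 0.05)
  after <- fit1$estimates$estimate[fit1$estimates$term == "outlier_corrected"]
  before <- fit1$estimates$estimate[fit1$estimates$term == "raw"]
  expect_lt(abs(after - 0.3), abs(before - 0.3))
  expect_false(is.na(fit1$distortion_p))
  expect_error(mr_presso(summ(c(0.2, 0.3, 0.4), c(1, 2, 3))), "at least 4")
})

test_that("tidy and glance methods expose estimates and diagnostics", {
  s <- summ(c(0.5, 0.25, 0.4), c(0.1, 0.05, 0.08))
  fit <- mr_ivw(s)
  td <- tidy(fit)
  expect_s3_class(td, "tbl_df")
  expect_equal(td$method, "ivw")
  gl <- glance(fit)
  expect_equal(gl$n_snps, 3L)
  expect_true(all(c("Q", "Q_df", "Q_p") %in% names(gl)))
  gp <- glance(mr_presso(summ(rep(0.5, 5), rep(0.1, 5)), n_sim = 100, seed = 1))
  expect_true(all(c("global_p", "n_outliers", "distortion_p") %in% names(gp)))
})
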