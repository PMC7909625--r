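check_summaries <- function(summaries, min_k = 2) {
  needed <- c("snp", "beta_exposure", "se_exposure",
              "beta_outcome", "se_outcome")
  stopifnot(all(needed %in% names(summaries)))
  if (nrow(summaries) < min_k) {
    stop("need at least ", min_k, " SNP summaries, got ", nrow(summaries),
         call. = FALSE)
  }
  if (any(summaries$se_exposure <= 0) || any(summaries$se_outcome <= 0)) {
    stop("summary standard errors must be positive", call. = FALSE)
  }
  invisible(summaries)
}

new_mr_fit <- function(method, estimates, heterogeneity = NULL, n_snps,
                       ..., subclass = NULL) {
  structure(
    list(method = method, estimates = estimates,
         heterogeneity = heterogeneity, n_snps = n_snps, ...),
    class = c(subclass, "mr_fit")
  )
}

#' @export
print.mr_fit <- function(x, digits = 4, ...) {
  cat("<mr_fit> method: ", x$method, " (", x$n_snps, " SNPs)\n", sep = "")
  print(as.data.frame(x$estimates), digits = digits, row.names = FALSE)
  if (!is.null(x$heterogeneity)) {
    cat(sprintf("Cochran's Q = %.*g on %d df (p = %.*g)\n", digits,
                x$heterogeneity$Q, x$heterogeneity$df, digits,
                x$heterogeneity$p))
  }
  invisible(x)
}

#' @importFrom generics tidy
#' @export
tidy.mr_fit <- function(x, ...) {
  dplyr::mutate(x$estimates, method = x$method, .before = 1)
}

#' @importFrom generics glance
#' @export
glance.mr_fit <- function(x, ...) {
  tibble::tibble(
    method = x$method, n_snps = x$n_snps,
    Q = if (is.null(x$heterogeneity)) NA_real_ else x$heterogeneity$Q,
    Q_df = if (is.null(x$heterogeneity)) NA_integer_ else x$heterogeneity$df,
    Q_p = if (is.null(x$heterogeneity)) NA_real_ else x$heterogeneity$p
  )
}

#' Per-SNP Wald ratio estimates
#'
#' The building block of every summary-data estimator: the per-SNP causal
#' estimate \eqn{\beta_{Yj}/\beta_{Xj}} with first-order delta-method standard
#' error \eqn{se_{Yj}/|\beta_{Xj}|}. Jointly flipping the signs of both
#' associations leaves the ratio unchanged.
#'
#' @param summaries A `snp_summaries` tibble (see [snp_summary_stats()]).
#' @return A tibble: `snp`, `estimate`, `std.error`, `conf.low`, `conf.high`,
#'   `p.value`.
#' @export
wald_ratio <- function(summaries) {
  check_summaries(summaries, min_k = 1)
  if (any(summaries$beta_exposure == 0)) {
    stop("Wald ratio undefined: beta_exposure is zero for ",
         paste(summaries$snp[summaries$beta_exposure == 0], collapse = ", "),
         call. = FALSE)
  }
  est <- summaries$beta_outcome / summaries$beta_exposure
  se <- summaries$se_outcome / abs(summaries$beta_exposure)
  z <- stats::qnorm(0.975)
  tibble::tibble(
    snp = summaries$snp, estimate = est, std.error = se,
    conf.low = est - z * se, conf.high = est + z * se,
    p.value = 2 * stats::pnorm(abs(est / se), lower.tail = FALSE)
  )
}

#' Cochran's Q heterogeneity statistic
#'
#' \eqn{Q = \sum_j w_j (r_j - \beta_{ref})^2} over the per-SNP Wald ratios
#' \eqn{r_j}, with inverse delta-method-variance weights
#' \eqn{w_j = \beta_{Xj}^2 / se_{Yj}^2}; under homogeneity Q is chi-squared
#' with K-1 degrees of freedom. Large Q flags SNPs whose ratio estimates
#' disagree, a symptom of pleiotropy or distinct causal pathways.
#'
#' @param summaries A `snp_summaries` tibble.
#' @param beta_ref Reference causal estimate (usually the IVW estimate).
#' @return A tibble: `Q`, `df`, `p`.
#' @export
cochran_q <- function(summaries, beta_ref) {
  check_summaries(summaries, min_k = 2)
  r <- summaries$beta_outcome / summaries$beta_exposure
  w <- summaries$beta_exposure^2 / summaries$se_outcome^2
  Q <- sum(w * (r - beta_ref)^2)
  df <- nrow(summaries) - 1L
  tibble::tibble(Q = Q, df = df,
                 p = stats::pchisq(Q, df, lower.tail = FALSE))
}

#' Inverse-variance-weighted (IVW) estimate
#'
#' Fixed-effect IVW: the precision-weighted mean of the per-SNP Wald ratios,
#' \deqn{\hat\beta = \frac{\sum_j \beta_{Xj}\beta_{Yj}/se_{Yj}^2}
#'                        {\sum_j \beta_{Xj}^2/se_{Yj}^2},\quad
#'       se = \sqrt{1 / \sum_j \beta_{Xj}^2/se_{Yj}^2}}
#' with a normal CI. With fully independent SNPs this is asymptotically
#' equivalent to 2SLS on the corresponding risk score. Cochran's Q against the
#' IVW estimate is returned alongside.
#'
#' @param summaries A `snp_summaries` tibble (at least 2 SNPs).
#' @return An object of class `mr_fit`.
#' @export
mr_ivw <- function(summaries) {
  check_summaries(summaries, min_k = 2)
  w_den <- sum(summaries$beta_exposure^2 / summaries$se_outcome^2)
  beta <- sum(summaries$beta_exposure * summaries$beta_outcome /
                summaries$se_outcome^2) / w_den
  se <- sqrt(1 / w_den)
  z <- stats::qnorm(0.975)
  est <- tibble::tibble(
    term = "causal_effect", estimate = beta, std.error = se,
    conf.low = beta - z * se, conf.high = beta + z * se,
    p.value = 2 * stats::pnorm(abs(beta / se), lower.tail = FALSE)
  )
  new_mr_fit("ivw", est, heterogeneity = cochran_q(summaries, beta),
             n_snps = nrow(summaries))
}

# interpolation rule on the standardized cumulative weights
weighted_median_point <- function(ratios, weights) {
  ord <- order(ratios)
  r <- ratios[ord]
  w <- weights[ord] / sum(weights)
  s <- cumsum(w) - w / 2
  k <- length(r)
  if (s[1] >= 0.5) return(r[1])
  if (s[k] <= 0.5) return(r[k])
  j <- max(which(s < 0.5))
  r[j] + (r[j + 1] - r[j]) * (0.5 - s[j]) / (s[j + 1] - s[j])
}

#' Weighted median estimate
#'
#' The causal estimate at the 50th percentile of the inverse-variance-weight-
#' standardized distribution of Wald ratios, computed by linear interpolation
#' of the cumulative weights. Consistent even when up to 50% of the weight
#' comes from invalid (pleiotropic) instruments. The standard error comes from
#' a seeded parametric bootstrap that redraws each summary association from
#' \eqn{N(\hat\beta_j, se_j)}.
#'
#' @param summaries A `snp_summaries` tibble (at least 3 SNPs).
#' @param n_boot Parametric bootstrap draws for the SE (default 1000;
#'   0 skips the SE and returns only the point estimate).
#' @param seed Optional integer seed; `NULL` uses the current RNG state.
#' @return An object of class `mr_fit`.
#' @export
mr_weighted_median <- function(summaries, n_boot = 1000, seed = NULL) {
  check_summaries(summaries, min_k = 3)
  if (any(summaries$beta_exposure == 0)) {
    stop("weighted median undefined with beta_exposure = 0", call. = FALSE)
  }
  r <- summaries$beta_outcome / summaries$beta_exposure
  w <- summaries$beta_exposure^2 / summaries$se_outcome^2
  beta <- weighted_median_point(r, w)
  se <- NA_real_
  if (n_boot > 0) {
    if (!is.null(seed)) set.seed(seed)
    k <- nrow(summaries)
    bx <- matrix(stats::rnorm(n_boot * k, mean = summaries$beta_exposure,
                              sd = summaries$se_exposure),
                 nrow = k)
    by <- matrix(stats::rnorm(n_boot * k, mean = summaries$beta_outcome,
                              sd = summaries$se_outcome),
                 nrow = k)
    draws <- vapply(seq_len(n_boot), function(b) {
      bxb <- bx[, b]
      if (any(bxb == 0)) return(NA_real_)
      weighted_median_point(by[, b] / bxb, bxb^2 / summaries$se_outcome^2)
    }, 0)
    se <- stats::sd(draws, na.rm = TRUE)
  }
  z <- stats::qnorm(0.975)
  est <- tibble::tibble(
    term = "causal_effect", estimate = beta, std.error = se,
    conf.low = beta - z * se, conf.high = beta + z * se,
    p.value = 2 * stats::pnorm(abs(beta / se), lower.tail = FALSE)
  )
  new_mr_fit("weighted_median", est, n_snps = nrow(summaries),
             n_boot = n_boot)
}

#' MR-Egger regression
#'
#' Weighted regression of the per-SNP outcome associations on the exposure
#' associations, with an intercept, using weights \eqn{1/se_{Yj}^2}. Summaries
#' are first oriented so every exposure association is non-negative (flipping
#' both betas jointly), which makes the intercept interpretable as the average
#' directional pleiotropic effect per allele; the slope is the
#' pleiotropy-adjusted causal estimate. Standard errors use the conventional
#' multiplicative random-effects scheme (residual dispersion estimated from
#' the weighted fit) with t-based inference on K-2 degrees of freedom.
#' Ruecker's Q about the Egger fit (df K-2) is returned as the heterogeneity
#' diagnostic.
#'
#' @param summaries A `snp_summaries` tibble (at least 3 SNPs).
#' @return An object of class `mr_egger`/`mr_fit` whose `estimates` has rows
#'   `slope` and `intercept`.
#' @export
mr_egger <- function(summaries) {
  check_summaries(summaries, min_k = 3)
  flip <- sign(summaries$beta_exposure)
  flip[flip == 0] <- 1
  bx <- summaries$beta_exposure * flip
  by <- summaries$beta_outcome * flip
  if (stats::sd(bx) == 0) {
    stop("MR-Egger undefined: no spread in exposure associations",
         call. = FALSE)
  }
  w <- 1 / summaries$se_outcome^2
  sw <- sqrt(w)
  X <- cbind(intercept = sw, slope = bx * sw)
  fit <- ols_fit(by * sw, X)
  df <- nrow(summaries) - 2L
  # multiplicative random-effects (estimated residual dispersion) SEs with
  # t-inference on K - 2 df: exactly calibrated under homogeneity and
  # conservative under overdispersion
  se <- fit$se
  tq <- stats::qt(0.975, df)
  est <- tibble::tibble(
    term = c("slope", "intercept"),
    estimate = unname(fit$coef[c("slope", "intercept")]),
    std.error = unname(se[c(2, 1)])
  ) |>
    dplyr::mutate(
      conf.low = .data$estimate - tq * .data$std.error,
      conf.high = .data$estimate + tq * .data$std.error,
      p.value = 2 * stats::pt(abs(.data$estimate / .data$std.error), df,
                              lower.tail = FALSE)
    )
  Qp <- fit$rss  # residuals of the scaled fit are already weight-scaled
  het <- tibble::tibble(Q = Qp, df = df,
                        p = stats::pchisq(Qp, df, lower.tail = FALSE))
  new_mr_fit("egger", est, heterogeneity = het, n_snps = nrow(summaries),
             subclass = "mr_egger")
}

ivw_beta <- function(bx, by, seY) {
  sum(bx * by / seY^2) / sum(bx^2 / seY^2)
}

#' MR-PRESSO: pleiotropy residual sum and outliers test
#'
#' Simulation-based pleiotropy diagnostic. The observed residual sum of
#' squares (RSS) of the outcome associations about their leave-one-out IVW
#' predictions, weighted by \eqn{1/se_{Yj}^2}, is compared against its null
#' distribution from `n_sim` parametric redraws of the summaries (global
#' test). Each SNP's squared residual is compared against its simulated
#' distribution to give Bonferroni-adjusted outlier p-values; flagged outliers
#' are removed and the IVW estimate recomputed (outlier-corrected estimate).
#' The distortion p-value compares the observed before/after shift against
#' shifts obtained by removing random SNP subsets of the same size.
#'
#' @param summaries A `snp_summaries` tibble (at least 4 SNPs).
#' @param n_sim Parametric simulations (default 1000).
#' @param outlier_alpha Significance level for the Bonferroni-adjusted
#'   per-SNP outlier test (default 0.05).
#' @param seed Optional integer seed; `NULL` uses the current RNG state.
#' @return An object of class `mr_presso`/`mr_fit`: `estimates` rows `raw`
#'   and `outlier_corrected`; fields `global_rss`, `global_p`, `outliers`
#'   (per-SNP tibble), `distortion_p`.
#' @export
mr_presso <- function(summaries, n_sim = 1000, outlier_alpha = 0.05,
                      seed = NULL) {
  check_summaries(summaries, min_k = 4)
  if (!is.null(seed)) set.seed(seed)
  k <- nrow(summaries)
  bx <- summaries$beta_exposure
  by <- summaries$beta_outcome
  seX <- summaries$se_exposure
  seY <- summaries$se_outcome
  w <- 1 / seY^2

  num <- sum(bx * by * w); den <- sum(bx^2 * w)
  loo <- (num - bx * by * w) / (den - bx^2 * w)
  resid_obs <- by - loo * bx
  rss_obs <- sum(w * resid_obs^2)

  # parametric null: redraw both associations, outcome centred on the
  # leave-one-out IVW prediction
  BX <- matrix(stats::rnorm(n_sim * k, mean = rep(bx, each = n_sim),
                            sd = rep(seX, each = n_sim)), nrow = n_sim)
  BY <- matrix(stats::rnorm(n_sim * k, mean = rep(loo * bx, each = n_sim),
                            sd = rep(seY, each = n_sim)), nrow = n_sim)
  W <- matrix(w, n_sim, k, byrow = TRUE)
  numM <- rowSums(BX * BY * W); denM <- rowSums(BX^2 * W)
  LOO <- (numM - BX * BY * W) / (denM - BX^2 * W)
  E <- BY - LOO * BX
  rss_sim <- rowSums(W * E^2)
  global_p <- (1 + sum(rss_sim >= rss_obs)) / (n_sim + 1)

  sq_obs <- w * resid_obs^2
  sq_sim <- W * E^2
  p_out <- (1 + colSums(sq_sim >= matrix(sq_obs, n_sim, k, byrow = TRUE))) /
    (n_sim + 1)
  p_adj <- pmin(1, p_out * k)
  is_out <- p_adj < outlier_alpha

  beta_before <- ivw_beta(bx, by, seY)
  keep <- !is_out
  distortion_p <- NA_real_
  if (any(is_out) && sum(keep) >= 2) {
    beta_after <- ivw_beta(bx[keep], by[keep], seY[keep])
    d_obs <- beta_before - beta_after
    n_out <- sum(is_out)
    d_sim <- vapply(seq_len(n_sim), function(i) {
      drop_idx <- sample.int(k, n_out)
      beta_before - ivw_beta(bx[-drop_idx], by[-drop_idx], seY[-drop_idx])
    }, 0)
    distortion_p <- (1 + sum(abs(d_sim) >= abs(d_obs))) / (n_sim + 1)
  } else {
    if (any(is_out)) warning("too few SNPs left after outlier removal; ",
                             "keeping the raw estimate")
    keep <- rep(TRUE, k)
    beta_after <- beta_before
  }
  se_before <- sqrt(1 / sum(bx^2 * w))
  se_after <- sqrt(1 / sum(bx[keep]^2 * w[keep]))
  z <- stats::qnorm(0.975)
  est <- tibble::tibble(
    term = c("raw", "outlier_corrected"),
    estimate = c(beta_before, beta_after),
    std.error = c(se_before, se_after)
  ) |>
    dplyr::mutate(
      conf.low = .data$estimate - z * .data$std.error,
      conf.high = .data$estimate + z * .data$std.error,
      p.value = 2 * stats::pnorm(abs(.data$estimate / .data$std.error),
                                 lower.tail = FALSE)
    )
  outliers <- tibble::tibble(
    snp = summaries$snp, residual = resid_obs, p.value = p_out,
    p.adjusted = p_adj, outlier = is_out
  )
  new_mr_fit("presso", est, n_snps = k, subclass = "mr_presso",
             global_rss = rss_obs, global_p = global_p, outliers = outliers,
             distortion_p = distortion_p, n_sim = n_sim)
}

#' @export
glance.mr_presso <- function(x, ...) {
  tibble::tibble(
    method = x$method, n_snps = x$n_snps, global_rss = x$global_rss,
    global_p = x$global_p, n_outliers = sum(x$outliers$outlier),
    distortion_p = x$distortion_p
  )
}

#' Leave-one-out IVW analysis
#'
#' Recomputes the IVW estimate (and Cochran's Q) K times, each time excluding
#' one SNP. A single SNP driving the pooled estimate or its heterogeneity
#' shows up as the row with a shifted estimate or a sharply reduced Q.
#'
#' @param summaries A `snp_summaries` tibble (at least 3 SNPs).
#' @return A tibble with one row per excluded SNP: `excluded_snp`,
#'   `estimate`, `std.error`, `conf.low`, `conf.high`, `p.value`, `Q`, `Q_p`.
#' @export
leave_one_out <- function(summaries) {
  check_summaries(summaries, min_k = 3)
  purrr::map_dfr(seq_len(nrow(summaries)), function(j) {
    fit <- mr_ivw(summaries[-j, ])
    dplyr::mutate(
      dplyr::select(fit$estimates, -"term"),
      excluded_snp = summaries$snp[j], .before = 1,
    ) |>
      dplyr::mutate(Q = fit$heterogeneity$Q, Q_p = fit$heterogeneity$p)
  })
}
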