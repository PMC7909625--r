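#' Covariate-adjustment model specifications
#'
#' The four specifications used throughout the analysis, differing in how
#' birth-cohort effects and education are handled:
#' \describe{
#'   \item{Model 1}{exposure AAM in years; birth-year dummies + 5-level
#'     education.}
#'   \item{Model 2}{exposure AAM in years; data-driven birth-cohort dummies +
#'     generation-relative highly-educated indicator.}
#'   \item{Model 3}{exposure gsAAM (already generation-standardized); 5-level
#'     education.}
#'   \item{Model 4}{exposure gsAAM; highly-educated indicator.}
#' }
#' Year and cohort variables enter as dummy indicators; the 5-level education
#' code enters as a factor.
#'
#' @param model Integer 1-4.
#' @return A list of class `model_spec` with `model`, `exposure`,
#'   `covariates` and `factors` fields.
#' @export
model_spec <- function(model) {
  model <- as.integer(model)
  if (length(model) != 1 || !model %in% 1:4) {
    stop("model must be one of 1, 2, 3, 4", call. = FALSE)
  }
  spec <- switch(model,
    list(model = 1L, exposure = "aam",
         covariates = c("birth_year", "education"),
         factors = c("birth_year", "education")),
    list(model = 2L, exposure = "aam",
         covariates = c("cohort", "highly_educated"),
         factors = "cohort"),
    list(model = 3L, exposure = "gsaam",
         covariates = "education",
         factors = "education"),
    list(model = 4L, exposure = "gsaam",
         covariates = "highly_educated",
         factors = character())
  )
  class(spec) <- "model_spec"
  spec
}

resolve_exposure <- function(spec, exposure) {
  if (!is.null(spec)) spec$exposure else exposure
}

assemble_design <- function(data, spec, exposure, extra = NULL) {
  expo <- resolve_exposure(spec, exposure)
  needed <- c(expo, "bmi_young_adult", if (!is.null(spec)) spec$covariates)
  missing_cols <- setdiff(needed, names(data))
  if (length(missing_cols) > 0) {
    stop("missing required column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  C <- if (!is.null(spec)) {
    covariate_matrix(data, spec$covariates, spec$factors)
  } else {
    NULL
  }
  y <- data$bmi_young_adult
  x <- data[[expo]]
  keep <- !is.na(y) & !is.na(x)
  if (!is.null(C)) keep <- keep & stats::complete.cases(C)
  if (!is.null(extra)) keep <- keep & !is.na(extra)
  list(y = y[keep], x = x[keep],
       C = if (is.null(C)) NULL else C[keep, , drop = FALSE],
       extra = if (is.null(extra)) NULL else extra[keep],
       exposure = expo, n = sum(keep), keep = keep)
}

#' Observational (conventional) regression of BMI on the exposure
#'
#' Ordinary least squares of young-adult BMI on AAM or gsAAM with the
#' covariates of a [model_spec()], returning the exposure coefficient with
#' analytic 95% CI and p-value, plus the model R-squared. This is the
#' confounder-adjusted association a conventional epidemiological analysis
#' reports, against which the instrumental-variable estimates are contrasted.
#'
#' @param data Standardized phenotype table (see [standardize_cohort()]).
#' @param spec A [model_spec()], or `NULL` for an unadjusted regression.
#' @param exposure Exposure column when `spec` is `NULL` (default `"aam"`).
#' @return A one-row tibble of class `mr_estimate`: `method`, `model`,
#'   `exposure`, `estimate`, `std.error`, `conf.low`, `conf.high`, `p.value`,
#'   `r.squared`, `n`.
#' @export
fit_observational <- function(data, spec = model_spec(1), exposure = "aam") {
  d <- assemble_design(data, spec, exposure)
  if (d$n < (2 + if (is.null(d$C)) 0 else ncol(d$C)) + 2) {
    stop("too few complete cases for the model", call. = FALSE)
  }
  X <- cbind(1, d$x, d$C)
  colnames(X)[1:2] <- c("(Intercept)", d$exposure)
  fit <- ols_fit(d$y, X)
  est <- fit$coef[2]; se <- fit$se[2]
  tss <- sum((d$y - mean(d$y))^2)
  out <- tibble::tibble(
    method = "observational",
    model = if (is.null(spec)) NA_integer_ else spec$model,
    exposure = d$exposure,
    estimate = unname(est),
    std.error = unname(se),
    conf.low = unname(est - stats::qt(0.975, fit$df) * se),
    conf.high = unname(est + stats::qt(0.975, fit$df) * se),
    p.value = unname(2 * stats::pt(abs(est / se), fit$df, lower.tail = FALSE)),
    r.squared = 1 - fit$rss / tss,
    n = d$n
  )
  class(out) <- c("mr_estimate", class(out))
  out
}

tsls_point <- function(y, x, z, C) {
  X1 <- cbind(1, z, C)
  f1 <- qr(X1)
  xhat <- qr.fitted(f1, x)
  if (stats::var(xhat) < .Machine$double.eps * 100) {
    stop("degenerate first stage: fitted exposure has (near) zero variance",
         call. = FALSE)
  }
  X2 <- cbind(`(Intercept)` = 1, fitted_exposure = xhat, C)
  fit2 <- ols_fit(y, X2)
  list(beta = unname(fit2$coef[2]), coefs = fit2$coef, X2 = X2)
}

#' Two-stage least squares estimate of the causal effect
#'
#' Instrumental-variable regression of young-adult BMI on the exposure using
#' the genetic risk score. Stage 1 regresses the exposure on the instrument
#' plus covariates; stage 2 regresses BMI on the instrument-predicted exposure
#' plus the same covariates. The point estimate is the stage-2 coefficient on
#' the predicted exposure. With `n_boot > 0` (default 1000) the SE and
#' percentile CI come from a seeded nonparametric pairs bootstrap; with
#' `n_boot = 0` the analytic 2SLS standard error (structural residuals against
#' the observed exposure) is used with a normal CI.
#'
#' @param data Standardized phenotype table containing a `grs` column.
#' @param spec A [model_spec()], or `NULL` for no covariates.
#' @param exposure Exposure column when `spec` is `NULL`.
#' @param instrument `"quartile"` (default; the risk score enters stage 1
#'   quartile-coded 1-4) or `"continuous"`.
#' @param n_boot Bootstrap replications (default 1000; 0 = analytic SE).
#' @param seed Optional integer seed for the bootstrap; `NULL` uses the
#'   current RNG state.
#' @return A one-row tibble of class `mr_estimate` (same columns as
#'   [fit_observational()], plus `instrument` and `n_boot`).
#' @export
fit_2sls <- function(data, spec = model_spec(1), exposure = "aam",
                     instrument = c("quartile", "continuous"),
                     n_boot = 1000, seed = NULL) {
  instrument <- match.arg(instrument)
  if (!"grs" %in% names(data)) {
    stop("missing required column(s): grs", call. = FALSE)
  }
  z_all <- if (instrument == "quartile") {
    as.numeric(grs_quartiles(data$grs))
  } else {
    data$grs
  }
  d <- assemble_design(data, spec, exposure, extra = z_all)
  if (stats::var(d$extra) == 0) {
    stop("instrument does not vary", call. = FALSE)
  }
  pt <- tsls_point(d$y, d$x, d$extra, d$C)
  beta <- pt$beta
  p_cols <- ncol(pt$X2)
  # structural residuals use the observed exposure, not the fitted one
  u <- d$y - pt$X2 %*% pt$coefs -
    pt$coefs[2] * (d$x - pt$X2[, 2])
  tss <- sum((d$y - mean(d$y))^2)
  r2 <- 1 - sum(u^2) / tss

  if (n_boot > 0) {
    if (!is.null(seed)) set.seed(seed)
    n <- d$n
    boots <- vapply(seq_len(n_boot), function(b) {
      idx <- sample.int(n, n, replace = TRUE)
      tryCatch(
        tsls_point(d$y[idx], d$x[idx], d$extra[idx],
                   if (is.null(d$C)) NULL else d$C[idx, , drop = FALSE])$beta,
        error = function(e) NA_real_
      )
    }, 0)
    boots <- boots[!is.na(boots)]
    se <- stats::sd(boots)
    ci <- stats::quantile(boots, c(0.025, 0.975), names = FALSE)
    p <- 2 * stats::pnorm(abs(beta / se), lower.tail = FALSE)
  } else {
    sigma2 <- sum(u^2) / (d$n - p_cols)
    V <- chol2inv(chol(crossprod(pt$X2)))
    se <- sqrt(sigma2 * V[2, 2])
    ci <- beta + c(-1, 1) * stats::qnorm(0.975) * se
    p <- 2 * stats::pnorm(abs(beta / se), lower.tail = FALSE)
  }
  out <- tibble::tibble(
    method = "2sls",
    model = if (is.null(spec)) NA_integer_ else spec$model,
    exposure = d$exposure,
    instrument = instrument,
    estimate = beta,
    std.error = se,
    conf.low = ci[1],
    conf.high = ci[2],
    p.value = p,
    r.squared = r2,
    n = d$n,
    n_boot = as.integer(n_boot)
  )
  class(out) <- c("mr_estimate", class(out))
  out
}

#' Per-SNP exposure and outcome association summaries
#'
#' For each panel SNP, covariate-adjusted OLS of the exposure on the
#' effect-allele dosage and of young-adult BMI on the dosage, with standard
#' errors. These per-SNP summary statistics feed every summary-data MR
#' estimator ([mr_ivw()], [mr_weighted_median()], [mr_egger()],
#' [mr_presso()]). Adjustment uses the covariates of `spec` (via
#' Frisch-Waugh-Lovell residualization, identical to the full regression);
#' `spec = NULL` gives unadjusted associations. SNPs monomorphic in the
#' analysed sample are dropped with a warning.
#'
#' @param data Standardized phenotype table.
#' @param genotypes Dosage matrix, rows aligned with `data`.
#' @param panel Optional panel tibble restricting and ordering SNPs.
#' @param spec A [model_spec()] or `NULL`.
#' @param exposure Exposure column when `spec` is `NULL`.
#' @return A tibble of class `snp_summaries`: `snp`, `beta_exposure`,
#'   `se_exposure`, `beta_outcome`, `se_outcome`, `n`.
#' @export
snp_summary_stats <- function(data, genotypes, panel = NULL, spec = NULL,
                              exposure = "aam") {
  snps <- if (!is.null(panel)) panel$snp else colnames(genotypes)
  missing_snps <- setdiff(snps, colnames(genotypes))
  if (length(missing_snps) > 0) {
    stop("SNP(s) absent from genotype matrix: ",
         paste(missing_snps, collapse = ", "), call. = FALSE)
  }
  d <- assemble_design(data, spec, exposure)
  G <- genotypes[d$keep, snps, drop = FALSE]
  base <- if (is.null(d$C)) matrix(1, d$n, 1) else cbind(1, d$C)
  Q_full <- qr(base)

  one_snp <- function(g) {
    ok <- !is.na(g)
    gg <- g[ok]
    if (length(unique(gg)) < 2) return(NULL)
    complete <- all(ok)
    Q <- if (complete) Q_full else qr(base[ok, , drop = FALSE])
    rg <- qr.resid(Q, gg)
    sg2 <- sum(rg^2)
    if (sg2 < .Machine$double.eps * 100) return(NULL)
    df <- length(gg) - ncol(base) - 1
    res <- lapply(list(d$x[ok], d$y[ok]), function(v) {
      rv <- qr.resid(Q, v)
      b <- sum(rg * rv) / sg2
      rss <- sum((rv - b * rg)^2)
      c(b, sqrt(rss / df / sg2))
    })
    c(res[[1]], res[[2]], length(gg))
  }

  rows <- purrr::map(seq_along(snps), function(j) one_snp(G[, j]))
  names(rows) <- snps
  dropped <- snps[vapply(rows, is.null, TRUE)]
  if (length(dropped) > 0) {
    warning("dropped monomorphic/degenerate SNP(s): ",
            paste(dropped, collapse = ", "))
  }
  rows <- rows[!vapply(rows, is.null, TRUE)]
  out <- tibble::tibble(
    snp = names(rows),
    beta_exposure = unname(vapply(rows, `[`, 0, 1)),
    se_exposure = unname(vapply(rows, `[`, 0, 2)),
    beta_outcome = unname(vapply(rows, `[`, 0, 3)),
    se_outcome = unname(vapply(rows, `[`, 0, 4)),
    n = as.integer(vapply(rows, `[`, 0, 5))
  )
  attr(out, "exposure") <- resolve_exposure(spec, exposure)
  class(out) <- c("snp_summaries", class(out))
  out
}
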