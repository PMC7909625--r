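#' Genotype quality-control thresholds
#'
#' @param min_call_rate Minimum per-SNP genotyping call rate (exclusive,
#'   default 0.95).
#' @param min_maf Minimum minor allele frequency (exclusive, default 0.01).
#' @param min_hwe_p Minimum Hardy-Weinberg equilibrium test p-value
#'   (exclusive, default 1e-6).
#' @param min_sample_call_rate Samples with call rate at or below this are
#'   dropped before SNP metrics are computed (default 0.9).
#' @return A list of class `qc_criteria`.
#' @export
qc_criteria <- function(min_call_rate = 0.95, min_maf = 0.01,
                        min_hwe_p = 1e-6, min_sample_call_rate = 0.9) {
  vals <- c(min_call_rate, min_maf, min_hwe_p, min_sample_call_rate)
  if (any(vals < 0) || any(vals > 1)) {
    stop("all QC thresholds must lie in [0, 1]", call. = FALSE)
  }
  structure(list(min_call_rate = min_call_rate, min_maf = min_maf,
                 min_hwe_p = min_hwe_p,
                 min_sample_call_rate = min_sample_call_rate),
            class = "qc_criteria")
}

#' Hardy-Weinberg equilibrium test from genotype counts
#'
#' Tests observed genotype counts against the Hardy-Weinberg proportions
#' \eqn{(p^2, 2pq, q^2)} at the observed allele frequency. The default is the
#' 1-df chi-squared goodness-of-fit test used in array QC; `method = "exact"`
#' gives the conditional exact test (mid-less enumeration over heterozygote
#' counts). Monomorphic SNPs are in equilibrium by convention (p = 1).
#'
#' @param counts Length-3 vector of genotype counts: hom-reference (dosage 0),
#'   heterozygous (1), hom-effect (2).
#' @param method `"chisq"` (default) or `"exact"`.
#' @return The p-value.
#' @export
#' @examples
#' hwe_test(c(25, 50, 25))  # 1
#' hwe_test(c(50, 0, 50))   # ~0 (chi-squared = 100)
hwe_test <- function(counts, method = c("chisq", "exact")) {
  method <- match.arg(method)
  stopifnot(length(counts) == 3, all(counts >= 0))
  n <- sum(counts)
  if (n < 1) stop("total genotype count must be >= 1", call. = FALSE)
  p <- (2 * counts[1] + counts[2]) / (2 * n)
  if (p == 0 || p == 1) return(1)
  if (method == "chisq") {
    expected <- n * c(p^2, 2 * p * (1 - p), (1 - p)^2)
    chi2 <- sum((counts - expected)^2 / expected)
    return(stats::pchisq(chi2, df = 1, lower.tail = FALSE))
  }
  hwe_exact_p(counts)
}

# Conditional exact HWE test: enumerate heterozygote counts compatible with
# the observed allele counts, sum probabilities <= that of the observed table.
hwe_exact_p <- function(counts) {
  n <- sum(counts)
  n_rare <- min(2 * counts[1] + counts[2], 2 * counts[3] + counts[2])
  het_obs <- counts[2]
  hets <- seq(n_rare %% 2, n_rare, by = 2)
  # log-probabilities of each possible heterozygote count given allele counts
  logp <- vapply(hets, function(h) {
    hom_rare <- (n_rare - h) / 2
    hom_common <- n - h - hom_rare
    lgamma(n + 1) - lgamma(hom_rare + 1) - lgamma(h + 1) -
      lgamma(hom_common + 1) + h * log(2) +
      lgamma(n_rare + 1) + lgamma(2 * n - n_rare + 1) - lgamma(2 * n + 1)
  }, 0)
  prob <- exp(logp - max(logp))
  prob <- prob / sum(prob)
  p_obs <- prob[match(het_obs, hets)]
  min(1, sum(prob[prob <= p_obs + 1e-12]))
}

snp_qc_metrics <- function(g) {
  call_rate <- mean(!is.na(g))
  gg <- g[!is.na(g)]
  if (length(gg) == 0) {
    return(tibble::tibble(call_rate = 0, maf = NA_real_, hwe_p = NA_real_))
  }
  f <- mean(gg) / 2
  counts <- c(sum(gg == 0), sum(gg == 1), sum(gg == 2))
  tibble::tibble(call_rate = call_rate, maf = min(f, 1 - f),
                 hwe_p = hwe_test(counts))
}

#' Quality-control filter for a genotype matrix
#'
#' Drops samples whose call rate is at or below `min_sample_call_rate`, then
#' retains SNPs with call rate above `min_call_rate`, MAF above `min_maf` and
#' HWE p-value above `min_hwe_p`. Filtering is idempotent: running it on its
#' own output changes nothing.
#'
#' @param genotypes Numeric matrix of 0/1/2 dosages (samples x SNPs), `NA` for
#'   missing calls; column names are SNP ids.
#' @param criteria A [qc_criteria()] object.
#' @return A list of class `qc_result`: `genotypes` (filtered matrix), `snps`
#'   (retained ids), `report` (per-SNP tibble with metrics, status and failure
#'   reasons), `samples_dropped` (ids).
#' @export
qc_filter_snps <- function(genotypes, criteria = qc_criteria()) {
  stopifnot(is.matrix(genotypes), nrow(genotypes) > 0, ncol(genotypes) > 0)
  if (is.null(colnames(genotypes))) {
    colnames(genotypes) <- paste0("snp", seq_len(ncol(genotypes)))
  }
  sample_cr <- rowMeans(!is.na(genotypes))
  keep_sample <- sample_cr > criteria$min_sample_call_rate
  if (!any(keep_sample)) {
    stop("all samples fail the sample call-rate threshold", call. = FALSE)
  }
  dropped <- rownames(genotypes)[!keep_sample]
  if (is.null(dropped)) dropped <- which(!keep_sample)
  g <- genotypes[keep_sample, , drop = FALSE]

  report <- purrr::map_dfr(seq_len(ncol(g)), function(j) {
    m <- snp_qc_metrics(g[, j])
    fails <- character()
    if (!isTRUE(m$call_rate > criteria$min_call_rate)) {
      fails <- c(fails, "call_rate")
    }
    if (!isTRUE(m$maf > criteria$min_maf)) fails <- c(fails, "maf")
    if (!isTRUE(m$hwe_p > criteria$min_hwe_p)) fails <- c(fails, "hwe")
    tibble::tibble(
      snp = colnames(g)[j],
      call_rate = m$call_rate, maf = m$maf, hwe_p = m$hwe_p,
      status = if (length(fails) == 0) "pass" else "fail",
      reason = paste(fails, collapse = ";")
    )
  })
  keep <- report$status == "pass"
  out <- list(
    genotypes = g[, keep, drop = FALSE],
    snps = report$snp[keep],
    report = report,
    samples_dropped = dropped
  )
  class(out) <- "qc_result"
  out
}

#' @export
print.qc_result <- function(x, ...) {
  cat("<qc_result> ", length(x$snps), "/", nrow(x$report), " SNPs retained, ",
      length(x$samples_dropped), " sample(s) dropped\n", sep = "")
  print(x$report)
  invisible(x)
}

# Per-column simple regression of y on each dosage column, via sufficient
# statistics on pairwise-complete observations. Returns beta, se, p per SNP.
fast_dosage_assoc <- function(y, G) {
  k <- ncol(G)
  beta <- se <- p <- n_used <- numeric(k)
  for (j in seq_len(k)) {
    g <- G[, j]
    ok <- !is.na(g) & !is.na(y)
    gg <- g[ok]; yy <- y[ok]
    n <- length(gg)
    vg <- stats::var(gg)
    if (n < 3 || !isTRUE(vg > 0)) {
      beta[j] <- NA_real_; se[j] <- NA_real_; p[j] <- NA_real_; n_used[j] <- n
      next
    }
    b <- stats::cov(gg, yy) / vg
    a <- mean(yy) - b * mean(gg)
    rss <- sum((yy - a - b * gg)^2)
    s2 <- rss / (n - 2)
    seb <- sqrt(s2 / ((n - 1) * vg))
    beta[j] <- b; se[j] <- seb
    p[j] <- 2 * stats::pt(abs(b / seb), df = n - 2, lower.tail = FALSE)
    n_used[j] <- n
  }
  tibble::tibble(snp = colnames(G), beta = beta, se = se, p = p, n = n_used)
}

#' Replication filter for candidate AAM SNPs
#'
#' Regresses AAM on the effect-allele dosage of each candidate SNP and keeps
#' those replicating at `p < alpha` with a coefficient sign matching the
#' published direction of association. SNPs on the `exclude` list (e.g. known
#' pleiotropic loci reported to act directly on adult BMI) are then removed;
#' that list is a user input, since pleiotropy evidence is external.
#'
#' @param panel Candidate panel tibble with `snp` and `published_direction`
#'   (+1/-1) columns.
#' @param data Phenotype table with an `aam` column.
#' @param genotypes Dosage matrix, rows aligned with `data`.
#' @param alpha Replication significance level (default 0.05).
#' @param exclude Character vector of SNP ids to drop after replication.
#' @return The replicated panel (filtered rows of `panel`) with `beta`, `se`,
#'   `p` columns appended; the full per-SNP table is attached as attribute
#'   `"report"`. Empty results warn.
#' @export
replicate_snps <- function(panel, data, genotypes, alpha = 0.05,
                           exclude = NULL) {
  stopifnot(all(c("snp", "published_direction") %in% names(panel)))
  missing_snps <- setdiff(panel$snp, colnames(genotypes))
  if (length(missing_snps) > 0) {
    stop("candidate SNP(s) absent from genotype matrix: ",
         paste(missing_snps, collapse = ", "), call. = FALSE)
  }
  assoc <- fast_dosage_assoc(data$aam, genotypes[, panel$snp, drop = FALSE])
  report <- panel |>
    dplyr::left_join(assoc, by = "snp") |>
    dplyr::mutate(
      replicated = !is.na(.data$p) & .data$p < alpha &
        sign(.data$beta) == .data$published_direction,
      excluded = .data$snp %in% exclude
    )
  out <- dplyr::filter(report, .data$replicated & !.data$excluded)
  if (nrow(out) == 0) warning("no SNPs survive replication filtering")
  attr(out, "report") <- report
  out
}

#' Unweighted genetic risk score for earlier menarche
#'
#' Counts AAM-decreasing alleles across the panel SNPs. Dosages of SNPs whose
#' effect allele *increases* AAM (`published_direction = +1`) are flipped to
#' `2 - G` so that a higher score always predicts earlier menarche. Missing
#' dosages are mean-imputed per SNP. An effect-size-weighted variant (weights
#' `|beta|` from the panel's `beta` column) is available behind `weighted`.
#'
#' @param genotypes Dosage matrix (samples x SNPs).
#' @param panel Panel tibble with `snp` and `published_direction`; a `beta`
#'   column is required when `weighted = TRUE`.
#' @param weighted Weight flipped dosages by `|beta|` (default `FALSE`,
#'   matching a plain allele count).
#' @return Numeric vector of scores, one per sample.
#' @export
build_grs <- function(genotypes, panel, weighted = FALSE) {
  stopifnot(all(c("snp", "published_direction") %in% names(panel)))
  missing_snps <- setdiff(panel$snp, colnames(genotypes))
  if (length(missing_snps) > 0) {
    stop("panel SNP(s) absent from genotype matrix: ",
         paste(missing_snps, collapse = ", "), call. = FALSE)
  }
  G <- genotypes[, panel$snp, drop = FALSE]
  for (j in seq_len(ncol(G))) {
    gj <- G[, j]
    if (anyNA(gj)) gj[is.na(gj)] <- mean(gj, na.rm = TRUE)
    if (panel$published_direction[j] > 0) gj <- 2 - gj
    G[, j] <- gj
  }
  if (weighted) {
    if (!"beta" %in% names(panel)) {
      stop("weighted GRS needs a 'beta' column in the panel", call. = FALSE)
    }
    drop(G %*% abs(panel$beta))
  } else {
    rowSums(G)
  }
}

#' Quartile-code a genetic risk score
#'
#' Rank-based quartiles 1-4; tied values all take the lower quartile (ties use
#' minimum rank). Quartile sizes are within one of n/4 in the absence of ties.
#'
#' @param grs Numeric vector with at least 4 distinct values.
#' @return Integer vector of quartiles, non-decreasing in `grs`.
#' @export
grs_quartiles <- function(grs) {
  if (length(unique(grs[!is.na(grs)])) < 4) {
    stop("need at least 4 distinct GRS values to form quartiles",
         call. = FALSE)
  }
  r <- rank(grs, ties.method = "min", na.last = "keep")
  as.integer(ceiling(4 * r / sum(!is.na(grs))))
}

#' First-stage instrument diagnostics
#'
#' Regresses the exposure on the risk score, both as a continuous per-unit
#' score and quartile-coded, optionally adjusting for covariates. Reports the
#' instrument coefficient with its 95% CI, the instrument's partial
#' F-statistic (the weak-instrument diagnostic; values above 10 are the
#' conventional comfort zone) and the model R-squared.
#'
#' @param data Phenotype table containing the exposure and any covariates.
#' @param grs Numeric risk score aligned with `data`.
#' @param exposure Name of the exposure column (default `"aam"`).
#' @param covariates Character vector of covariate column names (default
#'   none).
#' @return A tibble of class `first_stage`: one row per coding
#'   (`per_unit`, `per_quartile`) with `estimate`, `conf.low`, `conf.high`,
#'   `p.value`, `F`, `r.squared`, `n`.
#' @export
first_stage_diagnostics <- function(data, grs, exposure = "aam",
                                    covariates = NULL) {
  stopifnot(exposure %in% names(data))
  codings <- list(per_unit = grs, per_quartile = as.numeric(grs_quartiles(grs)))
  out <- purrr::imap_dfr(codings, function(z, nm) {
    df <- data.frame(.y = data[[exposure]], .z = z)
    cov_mm <- covariate_matrix(data, covariates)
    X <- cbind(`(Intercept)` = 1, .z = df$.z, cov_mm)
    ok <- stats::complete.cases(X) & !is.na(df$.y)
    X <- X[ok, , drop = FALSE]; y <- df$.y[ok]
    n <- length(y)
    if (n <= ncol(X)) stop("too few complete cases for the first stage",
                           call. = FALSE)
    fit <- ols_fit(y, X)
    # partial F of the instrument: compare against the covariate-only model
    X0 <- X[, -2, drop = FALSE]
    fit0 <- ols_fit(y, X0)
    Fstat <- ((fit0$rss - fit$rss) / 1) / (fit$rss / fit$df)
    tss <- sum((y - mean(y))^2)
    est <- unname(fit$coef[2]); se <- unname(fit$se[2])
    tibble::tibble(
      coding = nm,
      estimate = est,
      conf.low = est - stats::qt(0.975, fit$df) * se,
      conf.high = est + stats::qt(0.975, fit$df) * se,
      p.value = 2 * stats::pt(abs(est / se), fit$df, lower.tail = FALSE),
      F = Fstat,
      r.squared = 1 - fit$rss / tss,
      n = n
    )
  })
  class(out) <- c("first_stage", class(out))
  out
}

#' Confounder balance across the risk score
#'
#' The risk score is a valid instrument only if it is unrelated to
#' confounders of the exposure-outcome relationship. For each named
#' confounder this regresses the confounder on the score (numeric columns),
#' or runs a linear trend test on the ordinal codes (factor/ordered columns),
#' reporting the change per 1-unit score with 95% CI and p-value.
#'
#' @param data Phenotype table.
#' @param grs Numeric risk score aligned with `data`.
#' @param confounders Character vector of column names; an empty vector gives
#'   an empty table.
#' @return A tibble: `confounder`, `type`, `estimate`, `conf.low`,
#'   `conf.high`, `p.value`, `n`.
#' @export
confounder_balance <- function(data, grs, confounders) {
  if (length(confounders) == 0) {
    return(tibble::tibble(confounder = character(), type = character(),
                          estimate = numeric(), conf.low = numeric(),
                          conf.high = numeric(), p.value = numeric(),
                          n = integer()))
  }
  stopifnot(all(confounders %in% names(data)))
  purrr::map_dfr(confounders, function(v) {
    x <- data[[v]]
    type <- if (is.numeric(x)) "linear" else "trend"
    xv <- if (is.numeric(x)) x else as.numeric(factor(x))
    ok <- !is.na(xv) & !is.na(grs)
    X <- cbind(1, grs[ok])
    fit <- ols_fit(xv[ok], X)
    est <- fit$coef[2]; se <- fit$se[2]
    tibble::tibble(
      confounder = v, type = type, estimate = est,
      conf.low = est - stats::qt(0.975, fit$df) * se,
      conf.high = est + stats::qt(0.975, fit$df) * se,
      p.value = 2 * stats::pt(abs(est / se), fit$df, lower.tail = FALSE),
      n = sum(ok)
    )
  })
}
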