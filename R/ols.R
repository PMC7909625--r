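# Internal least-squares helpers shared by the diagnostics, the observational
# models and 2SLS. A thin QR wrapper is used instead of lm() so the same code
# path serves bootstrap loops and vectorized per-SNP scans without formula
# overhead, and so rank deficiency surfaces as an error naming the aliased
# columns rather than silent NA coefficients.

ols_fit <- function(y, X) {
  qrx <- qr(X)
  if (qrx$rank < ncol(X)) {
    aliased <- colnames(X)[qrx$pivot[(qrx$rank + 1):ncol(X)]]
    stop("design matrix is rank deficient; aliased column(s): ",
         paste(aliased, collapse = ", "), call. = FALSE)
  }
  coefs <- qr.coef(qrx, y)
  res <- y - drop(X %*% coefs)
  rss <- sum(res^2)
  df <- length(y) - ncol(X)
  s2 <- rss / df
  pv <- qrx$pivot
  xtx_inv <- matrix(NA_real_, ncol(X), ncol(X))
  xtx_inv[pv, pv] <- chol2inv(qr.R(qrx))
  list(coef = coefs, se = sqrt(pmax(diag(xtx_inv), 0) * s2),
       xtx_inv = xtx_inv, rss = rss, df = df, residuals = res,
       fitted = y - res)
}

# Expand covariate columns into a numeric design block (no intercept).
# Columns named in `factors` are dummy-coded; single-level factors are
# constants and contribute nothing (adjusting for a constant is a no-op).
covariate_matrix <- function(data, covariates, factors = character()) {
  if (is.null(covariates) || length(covariates) == 0) return(NULL)
  missing_cols <- setdiff(covariates, names(data))
  if (length(missing_cols) > 0) {
    stop("missing required column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  blocks <- lapply(covariates, function(v) {
    x <- data[[v]]
    if (v %in% factors || is.factor(x) || is.character(x)) {
      f <- droplevels(factor(x))
      if (nlevels(f) < 2) return(NULL)
      mm <- stats::model.matrix(
        ~f, stats::model.frame(~f, data.frame(f = f),
                               na.action = stats::na.pass))[, -1, drop = FALSE]
      colnames(mm) <- paste0(v, sub("^f", "", colnames(mm)))
      mm
    } else {
      m <- matrix(as.numeric(x), ncol = 1)
      colnames(m) <- v
      m
    }
  })
  blocks <- blocks[!vapply(blocks, is.null, TRUE)]
  if (length(blocks) == 0) return(NULL)
  do.call(cbind, blocks)
}
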