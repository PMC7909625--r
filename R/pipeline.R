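#' Run the full observational + MR model grid
#'
#' Fills the complete analysis report: for each requested model specification
#' (see [model_spec()]) the observational OLS estimate and the 2SLS estimate;
#' for each exposure form (AAM in years, gsAAM) the summary-data MR block
#' (IVW, weighted median, MR-Egger slope and intercept, MR-PRESSO, Cochran's
#' Q) and the leave-one-out table; first-stage instrument diagnostics; and the
#' confounder-balance table. One master seed fixes the 2SLS bootstrap, the
#' weighted-median bootstrap and the PRESSO simulations, so a rerun with the
#' same inputs reproduces the report exactly.
#'
#' Per-SNP summary statistics are adjusted with the cohort-level covariates of
#' Model 2 for the AAM exposure and of Model 4 for gsAAM (the cohort-relative
#' adjustment sets); pass `adjust_summaries = FALSE` for unadjusted summaries.
#'
#' @param data Standardized phenotype table with columns `aam`, `gsaam`,
#'   `bmi_young_adult`, `education`, `highly_educated`, `cohort`,
#'   `birth_year` and `grs`.
#' @param genotypes Dosage matrix aligned with `data`.
#' @param panel Instrument panel tibble (`snp`, `published_direction`, ...).
#' @param models Integer subset of 1:4 (default all).
#' @param n_boot Bootstrap replications for 2SLS and the weighted median
#'   (default 1000).
#' @param n_presso PRESSO simulations (default 1000).
#' @param instrument First-stage coding for 2SLS (default `"quartile"`).
#' @param adjust_summaries Adjust per-SNP summaries for cohort-level
#'   covariates (default `TRUE`).
#' @param confounders Columns for the balance table.
#' @param seed Master seed (default 1).
#' @return An object of class `mr_report`.
#' @export
run_models <- function(data, genotypes, panel, models = 1:4, n_boot = 1000,
                       n_presso = 1000, instrument = "quartile",
                       adjust_summaries = TRUE,
                       confounders = c("education", "highly_educated",
                                       "birth_year"),
                       seed = 1L) {
  required <- c("aam", "gsaam", "bmi_young_adult", "education",
                "highly_educated", "cohort", "birth_year", "grs")
  missing_cols <- setdiff(required, names(data))
  if (length(missing_cols) > 0) {
    stop("missing required column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  set.seed(seed)
  estimates <- purrr::map_dfr(models, function(m) {
    spec <- model_spec(m)
    dplyr::bind_rows(
      fit_observational(data, spec),
      fit_2sls(data, spec, instrument = instrument, n_boot = n_boot)
    )
  })

  adjustment <- list(aam = model_spec(2), gsaam = model_spec(4))
  adjusted <- purrr::imap(adjustment, function(spec, expo) {
    s <- snp_summary_stats(
      data, genotypes, panel,
      spec = if (adjust_summaries) spec else NULL,
      exposure = expo
    )
    ivw <- mr_ivw(s)
    list(
      summaries = s,
      ivw = ivw,
      weighted_median = mr_weighted_median(s, n_boot = n_boot),
      egger = mr_egger(s),
      presso = mr_presso(s, n_sim = n_presso),
      heterogeneity = ivw$heterogeneity,
      leave_one_out = leave_one_out(s)
    )
  })

  first_stage <- dplyr::bind_rows(
    dplyr::mutate(first_stage_diagnostics(data, data$grs, exposure = "aam"),
                  exposure = "aam", .before = 1),
    dplyr::mutate(first_stage_diagnostics(data, data$grs, exposure = "gsaam"),
                  exposure = "gsaam", .before = 1)
  )

  out <- list(
    estimates = estimates,
    adjusted = adjusted,
    first_stage = first_stage,
    confounders = confounder_balance(data, data$grs, confounders),
    metadata = list(
      seed = as.integer(seed),
      n = nrow(data),
      n_snps = nrow(panel),
      n_boot = as.integer(n_boot),
      n_presso = as.integer(n_presso),
      instrument = instrument,
      models = as.integer(models),
      input_hash = rlang::hash(list(data, genotypes, panel)),
      package_version = as.character(utils::packageVersion("menarcheMR"))
    )
  )
  class(out) <- "mr_report"
  out
}

#' @export
print.mr_report <- function(x, digits = 3, ...) {
  cat("<mr_report> n =", x$metadata$n, "participants,",
      x$metadata$n_snps, "instrument SNPs, seed", x$metadata$seed, "\n\n")
  cat("Observational and 2SLS estimates:\n")
  print(as.data.frame(x$estimates[, c("method", "model", "exposure",
                                      "estimate", "conf.low", "conf.high",
                                      "p.value")]),
        digits = digits, row.names = FALSE)
  for (expo in names(x$adjusted)) {
    cat("\nSummary-data MR (", expo, "):\n", sep = "")
    blk <- x$adjusted[[expo]]
    tab <- dplyr::bind_rows(tidy(blk$ivw), tidy(blk$weighted_median),
                            tidy(blk$egger), tidy(blk$presso))
    print(as.data.frame(tab), digits = digits, row.names = FALSE)
  }
  invisible(x)
}

#' Plot-ready long table of every estimate in a report
#'
#' One row per estimate with its label, point estimate, CI bounds, analysis
#' type and model id — sufficient to draw a forest plot of the observational
#' versus MR contrast without recomputation. Values are carried over from the
#' report unchanged. Empty adjusted-MR blocks contribute no rows.
#'
#' @param report An [run_models()] report.
#' @return A tibble: `label`, `exposure`, `analysis` (`"observational"` or
#'   `"MR"`), `model`, `method`, `estimate`, `conf.low`, `conf.high`,
#'   `p.value`.
#' @export
forest_table <- function(report) {
  stopifnot(inherits(report, "mr_report"))
  primary <- report$estimates |>
    dplyr::transmute(
      label = paste0("Model ", .data$model, " (",
                     ifelse(.data$method == "2sls", "MR", "Obs"), ", ",
                     .data$exposure, ")"),
      exposure = .data$exposure,
      analysis = ifelse(.data$method == "2sls", "MR", "observational"),
      model = .data$model,
      method = .data$method,
      estimate = .data$estimate,
      conf.low = .data$conf.low,
      conf.high = .data$conf.high,
      p.value = .data$p.value
    )
  adjusted <- purrr::imap_dfr(report$adjusted, function(blk, expo) {
    if (is.null(blk)) return(NULL)
    tab <- dplyr::bind_rows(
      tidy(blk$ivw),
      tidy(blk$weighted_median),
      dplyr::filter(tidy(blk$egger), .data$term == "slope"),
      dplyr::mutate(
        dplyr::filter(tidy(blk$egger), .data$term == "intercept"),
        method = "egger_intercept"),
      dplyr::filter(tidy(blk$presso), .data$term == "outlier_corrected")
    )
    dplyr::transmute(
      tab,
      label = paste0(.data$method, " (", expo, ")"),
      exposure = expo,
      analysis = "MR",
      model = NA_integer_,
      method = .data$method,
      estimate = .data$estimate,
      conf.low = .data$conf.low,
      conf.high = .data$conf.high,
      p.value = .data$p.value
    )
  })
  dplyr::bind_rows(primary, adjusted)
}

#' @export
tidy.mr_report <- function(x, ...) forest_table(x)

#' @export
glance.mr_report <- function(x, ...) {
  tibble::as_tibble(x$metadata[c("seed", "n", "n_snps", "n_boot", "n_presso",
                                 "instrument", "input_hash",
                                 "package_version")])
}

#' Write report tables to CSV or JSON
#'
#' @param report An [run_models()] report.
#' @param path Output file path.
#' @param format `"csv"` writes the forest table; `"json"` writes the forest
#'   table, first-stage diagnostics, confounder balance, heterogeneity and
#'   metadata.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path, format = c("csv", "json")) {
  format <- match.arg(format)
  ft <- forest_table(report)
  if (format == "csv") {
    readr::write_csv(ft, path)
  } else {
    obj <- list(
      forest = as.data.frame(ft),
      first_stage = as.data.frame(report$first_stage),
      confounder_balance = as.data.frame(report$confounders),
      heterogeneity = lapply(report$adjusted,
                             function(b) as.data.frame(b$heterogeneity)),
      leave_one_out = lapply(report$adjusted,
                             function(b) as.data.frame(b$leave_one_out)),
      metadata = report$metadata
    )
    jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}
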