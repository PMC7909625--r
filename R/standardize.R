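#' Build a birth-year AAM reference table from individual data
#'
#' Summarises a phenotype table into the per-birth-year reference needed for
#' generation standardization: mean AAM, SD, the proportion with early
#' menarche (strictly `aam < 14`) and the count. Years with fewer than `min_n`
#' participants are pooled with the next year (the last sparse year with the
#' previous) before the mean/SD are computed, so no year's standardization
#' rests on a handful of observations; each year still gets its own row.
#'
#' @param data Data frame with columns `birth_year` and `aam`.
#' @param min_n Minimum participants per year before pooling (default 30).
#' @param early_cutoff Early-menarche threshold in years (default 14, strict
#'   `<`).
#' @return A tibble: `birth_year`, `mean_aam`, `sd_aam`, `prop_early`, `n`
#'   (the year's own count; pooled years share mean/SD/proportion).
#' @export
build_reference <- function(data, min_n = 30, early_cutoff = 14) {
  stopifnot(all(c("birth_year", "aam") %in% names(data)))
  tab <- data |>
    dplyr::count(.data$birth_year, name = "n_year") |>
    dplyr::arrange(.data$birth_year)
  years <- tab$birth_year
  # forward-merge sparse years into pooling groups
  group <- integer(length(years))
  g <- 1L
  acc <- 0L
  for (i in seq_along(years)) {
    group[i] <- g
    acc <- acc + tab$n_year[i]
    if (acc >= min_n && i < length(years)) {
      g <- g + 1L
      acc <- 0L
    }
  }
  # a trailing sparse group merges backwards
  if (acc < min_n && g > 1L) group[group == g] <- g - 1L
  lookup <- tibble::tibble(birth_year = years, .group = group)
  stats_by_group <- data |>
    dplyr::inner_join(lookup, by = "birth_year") |>
    dplyr::group_by(.data$.group) |>
    dplyr::summarise(
      mean_aam = mean(.data$aam),
      sd_aam = stats::sd(.data$aam),
      prop_early = mean(.data$aam < early_cutoff),
      .groups = "drop"
    )
  data |>
    dplyr::count(.data$birth_year, name = "n") |>
    dplyr::inner_join(lookup, by = "birth_year") |>
    dplyr::inner_join(stats_by_group, by = ".group") |>
    dplyr::transmute(
      birth_year = as.integer(.data$birth_year),
      mean_aam = .data$mean_aam,
      sd_aam = .data$sd_aam,
      prop_early = .data$prop_early,
      n = .data$n
    ) |>
    dplyr::arrange(.data$birth_year)
}

check_reference <- function(ref) {
  stopifnot(all(c("birth_year", "mean_aam", "sd_aam", "prop_early", "n")
                %in% names(ref)))
  if (nrow(ref) == 0) stop("reference population is empty", call. = FALSE)
  yrs <- sort(ref$birth_year)
  if (!identical(as.integer(yrs), as.integer(seq(min(yrs), max(yrs))))) {
    stop("reference birth years must form a contiguous integer range",
         call. = FALSE)
  }
  invisible(ref)
}

#' Generation-standardized age at menarche (gsAAM)
#'
#' Standardizes AAM against the birth-year reference distribution: the
#' individual AAM minus the mean AAM of the birth year, divided by that year's
#' SD. The result is a within-generation z-score, so gsAAM is comparable across
#' cohorts whose raw menarcheal ages differ by several years.
#'
#' @param aam Numeric vector of ages at menarche (years).
#' @param birth_year Integer vector, same length.
#' @param ref Reference table as produced by [build_reference()] or
#'   [simulate_reference_population()].
#' @return Numeric vector of z-scores.
#' @export
#' @examples
#' ref <- tibble::tibble(birth_year = 1950L, mean_aam = 15, sd_aam = 2,
#'                       prop_early = 0.05, n = 100L)
#' compute_gsaam(14, 1950, ref)  # -0.5
compute_gsaam <- function(aam, birth_year, ref) {
  check_reference(ref)
  idx <- match(birth_year, ref$birth_year)
  if (anyNA(idx)) {
    missing_years <- sort(unique(birth_year[is.na(idx)]))
    stop("birth year(s) not in reference: ",
         paste(missing_years, collapse = ", "), call. = FALSE)
  }
  sd_y <- ref$sd_aam[idx]
  if (any(!is.na(sd_y) & sd_y <= 0)) {
    bad <- sort(unique(ref$birth_year[idx][sd_y <= 0]))
    stop("reference sd_aam is zero for birth year(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  (aam - ref$mean_aam[idx]) / sd_y
}

#' Append a gsAAM column to a phenotype table
#'
#' @param data Data frame with `aam` and `birth_year` columns.
#' @param ref Reference table.
#' @return `data` with a `gsaam` column added.
#' @export
add_gsaam <- function(data, ref) {
  dplyr::mutate(data, gsaam = compute_gsaam(.data$aam, .data$birth_year, ref))
}

#' Segment birth years into cohorts by the early-menarche proportion
#'
#' Greedy left-to-right construction of birth cohorts with a homogeneous AAM
#' distribution. A cohort opens at the earliest unassigned year. If the opening
#' year's early-menarche proportion lies inside `[band_low, band_high]`, the
#' cohort is band-governed: it extends to the next year only while the pooled
#' (participant-weighted) early-menarche proportion of the open cohort stays
#' inside the band. Regardless of the band, the cohort closes before year K+1
#' whenever the per-year proportion at K+1 differs from that at K by more than
#' `jump_threshold`. Years opening outside the band (e.g. recent years where
#' early menarche exceeds 40%) form cohorts governed by the jump rule alone.
#' The final cohort runs to the last reference year.
#'
#' @param ref Reference table (contiguous years, `n >= 1` per year).
#' @param band_low,band_high Pooled early-menarche band (defaults 0.05, 0.06).
#' @param jump_threshold Maximum allowed year-on-year change in the per-year
#'   proportion (default 0.02).
#' @param band `"pooled"` (default) evaluates the band on the open cohort's
#'   pooled proportion; `"marginal"` on each candidate year's own proportion.
#' @return A tibble of class `birth_cohort_partition` with columns `cohort`
#'   (label), `start_year`, `end_year`; intervals tile the reference range.
#' @export
segment_birth_cohorts <- function(ref, band_low = 0.05, band_high = 0.06,
                                  jump_threshold = 0.02,
                                  band = c("pooled", "marginal")) {
  band <- match.arg(band)
  check_reference(ref)
  ref <- dplyr::arrange(ref, .data$birth_year)
  p <- ref$prop_early
  n <- ref$n
  k <- nrow(ref)
  starts <- 1L
  cur <- 1L
  if (k > 1) {
    governed <- p[1] >= band_low && p[1] <= band_high
    for (i in seq_len(k - 1)) {
      jump <- abs(p[i + 1] - p[i]) > jump_threshold
      if (band == "pooled") {
        pooled_next <- sum(p[cur:(i + 1)] * n[cur:(i + 1)]) / sum(n[cur:(i + 1)])
        band_exit <- governed && (pooled_next < band_low || pooled_next > band_high)
      } else {
        band_exit <- governed &&
          (p[i + 1] < band_low || p[i + 1] > band_high)
      }
      if (jump || band_exit) {
        cur <- i + 1L
        starts <- c(starts, cur)
        governed <- p[cur] >= band_low && p[cur] <= band_high
      }
    }
  }
  ends <- c(starts[-1] - 1L, k)
  out <- tibble::tibble(
    cohort = paste0(ref$birth_year[starts], "-", ref$birth_year[ends]),
    start_year = as.integer(ref$birth_year[starts]),
    end_year = as.integer(ref$birth_year[ends])
  )
  class(out) <- c("birth_cohort_partition", class(out))
  out
}

check_partition <- function(partition) {
  stopifnot(all(c("cohort", "start_year", "end_year") %in% names(partition)))
  if (nrow(partition) == 0) stop("empty partition", call. = FALSE)
  if (any(partition$start_year > partition$end_year)) {
    stop("partition has an interval with start > end", call. = FALSE)
  }
  if (nrow(partition) > 1) {
    gaps <- partition$start_year[-1] - partition$end_year[-nrow(partition)]
    if (any(gaps != 1L)) {
      stop("partition intervals must be contiguous and non-overlapping",
           call. = FALSE)
    }
  }
  invisible(partition)
}

#' Assign each participant to a birth cohort
#'
#' @param data Data frame with a `birth_year` column.
#' @param partition A [segment_birth_cohorts()] partition.
#' @return `data` with a `cohort` factor column (levels in year order).
#' @export
assign_cohort <- function(data, partition) {
  check_partition(partition)
  idx <- findInterval(data$birth_year, partition$start_year)
  out_of_range <- idx == 0 | data$birth_year > partition$end_year[pmax(idx, 1L)]
  if (any(out_of_range)) {
    stop("birth year(s) outside every cohort interval: ",
         paste(sort(unique(data$birth_year[out_of_range])), collapse = ", "),
         call. = FALSE)
  }
  dplyr::mutate(data, cohort = factor(partition$cohort[idx],
                                      levels = partition$cohort))
}

#' Derive a generation-relative education map from data
#'
#' The "highly educated" indicator is relative to each birth cohort: the
#' attainment that marks someone as highly educated among women born in the
#' 1930s (finishing elementary school) is not the one that does among women
#' born in the 1980s (university). Given the observed education distribution,
#' this picks, per cohort, the threshold level whose at-or-above share is
#' closest to one half — a majority split within the generation. Supply an
#' explicit map instead when thresholds are known a priori.
#'
#' @param data Data frame with `birth_year` and `education` (codes 1-5).
#' @param partition A [segment_birth_cohorts()] partition.
#' @return A tibble: `cohort`, `min_level` (code of the lowest level counted
#'   as highly educated).
#' @export
derive_education_map <- function(data, partition) {
  check_partition(partition)
  assign_cohort(data, partition) |>
    dplyr::group_by(.data$cohort) |>
    dplyr::summarise(
      min_level = {
        ed <- .data$education
        shares <- vapply(2:5, function(t) mean(ed >= t), 0)
        as.integer((2:5)[which.min(abs(shares - 0.5))])
      },
      .groups = "drop"
    ) |>
    dplyr::mutate(cohort = as.character(.data$cohort))
}

#' Flag participants as highly educated relative to their generation
#'
#' Returns 1 when education is at or above the cohort-specific threshold in
#' `map`, 0 otherwise.
#'
#' @param education Integer vector of education codes 1-5
#'   (see [education_levels()]).
#' @param birth_year Integer vector, same length.
#' @param partition A [segment_birth_cohorts()] partition.
#' @param map Tibble with `cohort` and `min_level` columns, e.g. from
#'   [derive_education_map()].
#' @return Integer vector of 0/1 indicators.
#' @export
flag_highly_educated <- function(education, birth_year, partition, map) {
  check_partition(partition)
  stopifnot(all(c("cohort", "min_level") %in% names(map)))
  if (!all(map$min_level %in% 1:5)) {
    stop("education map thresholds must be codes 1-5", call. = FALSE)
  }
  idx <- findInterval(birth_year, partition$start_year)
  bad <- idx == 0 | birth_year > partition$end_year[pmax(idx, 1L)]
  if (any(bad)) {
    stop("birth year(s) in no cohort interval: ",
         paste(sort(unique(birth_year[bad])), collapse = ", "), call. = FALSE)
  }
  thr <- map$min_level[match(partition$cohort[idx], map$cohort)]
  if (anyNA(thr)) {
    stop("education map is missing cohort(s): ",
         paste(setdiff(partition$cohort[idx], map$cohort), collapse = ", "),
         call. = FALSE)
  }
  as.integer(education >= thr)
}

#' Standardize a cohort for analysis
#'
#' Convenience wrapper that appends the three generation-relative columns the
#' analysis models need: `gsaam`, `cohort` and `highly_educated`.
#'
#' @param data Phenotype table (`birth_year`, `aam`, `education`, ...).
#' @param ref Reference table for standardization.
#' @param partition Optional partition; segmented from `ref` when `NULL`.
#' @param map Optional education map; derived from `data` when `NULL`.
#' @return `data` with `gsaam`, `cohort`, `highly_educated` columns, plus the
#'   partition and map attached as attributes `"partition"` and
#'   `"education_map"`.
#' @export
standardize_cohort <- function(data, ref, partition = NULL, map = NULL) {
  if (is.null(partition)) partition <- segment_birth_cohorts(ref)
  if (is.null(map)) map <- derive_education_map(data, partition)
  out <- data |>
    add_gsaam(ref) |>
    assign_cohort(partition) |>
    dplyr::mutate(highly_educated = flag_highly_educated(
      .data$education, .data$birth_year, partition, map))
  attr(out, "partition") <- partition
  attr(out, "education_map") <- map
  out
}

#' Serialize a partition and education map to JSON
#'
#' @param partition A [segment_birth_cohorts()] partition.
#' @param map Education map tibble (optional).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_partition_json <- function(partition, path, map = NULL) {
  check_partition(partition)
  obj <- list(partition = as.data.frame(partition))
  if (!is.null(map)) obj$education_map <- as.data.frame(map)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_partition_json
#' @export
read_partition_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  part <- tibble::as_tibble(obj$partition)
  part$start_year <- as.integer(part$start_year)
  part$end_year <- as.integer(part$end_year)
  class(part) <- c("birth_cohort_partition", class(part))
  out <- list(partition = part)
  if (!is.null(obj$education_map)) {
    out$education_map <- tibble::as_tibble(obj$education_map)
  }
  out
}
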