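# CSV interfaces for every stage, so the pipeline can be driven file-to-file
# (and from the thin command-line wrapper in inst/cli). Genotypes travel as an
# id x SNP matrix of 0/1/2 with missing calls as empty cells.

#' Write a simulated cohort to a directory of CSV files
#'
#' Creates `phenotypes.csv`, `genotypes.csv`, `panel.csv`, `reference.csv`
#' (the matching reference population) and `config.yaml` (with the seed) in
#' `dir`.
#'
#' @param sim A [simulate_cohort()] result.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(sim, dir) {
  stopifnot(inherits(sim, "sim_cohort"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  readr::write_csv(sim$phenotypes, file.path(dir, "phenotypes.csv"))
  geno <- tibble::as_tibble(sim$genotypes)
  geno <- dplyr::bind_cols(tibble::tibble(id = sim$phenotypes$id), geno)
  readr::write_csv(geno, file.path(dir, "genotypes.csv"), na = "")
  readr::write_csv(sim$panel, file.path(dir, "panel.csv"))
  readr::write_csv(simulate_reference_population(sim$config),
                   file.path(dir, "reference.csv"))
  write_sim_config(sim$config, file.path(dir, "config.yaml"))
  invisible(dir)
}

#' Read pipeline CSV inputs
#'
#' @param path CSV file path.
#' @return `read_phenotypes()`, `read_reference()` and `read_panel()` return
#'   tibbles; `read_genotypes()` returns a numeric matrix with sample ids as
#'   row names (empty cells become `NA`).
#' @export
read_phenotypes <- function(path) {
  readr::read_csv(path, show_col_types = FALSE)
}

#' @rdname read_phenotypes
#' @export
read_genotypes <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE, na = c("", "NA"))
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- as.character(df[[1]])
  m
}

#' @rdname read_phenotypes
#' @export
read_reference <- function(path) {
  ref <- readr::read_csv(path, show_col_types = FALSE)
  check_reference(ref)
  ref
}

#' @rdname read_phenotypes
#' @export
read_panel <- function(path) {
  readr::read_csv(path, show_col_types = FALSE)
}
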