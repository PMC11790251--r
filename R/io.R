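#' Read a trajectory/observation CSV
#'
#' Expected columns: `population`, `strain`, `generation`, `prop_reported`
#' and optionally `prop_total` (absent for real flow-cytometry data, which
#' only reports the fluorescent CNV class). Rows are validated and sorted by
#' generation within population.
#'
#' @param path CSV file path.
#' @return A tibble grouped-ready (one row per population x generation).
#' @export
read_observations <- function(path) {
  # base parser: correctly-rounded doubles, so written files reload bit-exact
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("population", "strain", "generation", "prop_reported")
  missing <- setdiff(need, names(df))
  if (length(missing))
    abort(paste0("missing column(s): ", paste(missing, collapse = ", ")))
  for (col in intersect(c("prop_reported", "prop_total"), names(df))) {
    bad <- which(!is.finite(df[[col]]) | df[[col]] < 0 | df[[col]] > 1)
    if (length(bad))
      abort(sprintf("`%s` outside [0, 1] at row %d", col, bad[1]))
  }
  df |>
    dplyr::arrange(.data$population, .data$generation) |>
    as_tibble()
}

#' Write a trajectory/observation CSV
#'
#' @param data Tibble with at least `population`, `strain`, `generation`,
#'   `prop_reported`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_observations <- function(data, path) {
  stopifnot(all(c("population", "strain", "generation", "prop_reported")
                %in% names(data)))
  readr::write_csv(data, path, progress = FALSE)
  invisible(path)
}

#' Serialize / restore a trained estimator
#'
#' The estimator is written as a single versioned RDS file.
#'
#' @param estimator A `cnv_estimator` from [train_density_estimator()].
#' @param path File path.
#' @return `path` / the estimator.
#' @export
write_estimator <- function(estimator, path) {
  stopifnot(inherits(estimator, "cnv_estimator"))
  saveRDS(estimator, path)
  invisible(path)
}

#' @rdname write_estimator
#' @export
read_estimator <- function(path) {
  est <- readRDS(path)
  if (!inherits(est, "cnv_estimator")) abort("not a cnv_estimator file")
  est
}

# Short stable hash of a configuration list, recorded in output artifacts so
# any run can be reproduced exactly.
config_hash <- function(config) substr(rlang::hash(config), 1, 12)
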