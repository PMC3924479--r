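#' Read an area table from CSV
#'
#' The area table holds one row per areal unit (here, census block groups)
#' with the observed event count, the population at risk (women aged 16 and
#' over), and any number of numeric covariate columns. Required columns are
#' `area_id`, `observed` and `population`; an `expected` column is optional
#' on input (it is derived by [compute_expected()]) and every remaining
#' numeric column is treated as a covariate.
#'
#' @param path Path to a CSV file (comma-separated, UTF-8, `.` decimal) with
#'   a header row.
#' @return A validated tibble in file order, with attribute `"covariates"`
#'   listing the covariate column names.
#' @export
read_area_table <- function(path) {
  if (!file.exists(path)) stop("area table file not found: ", path)
  tab <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  validate_area_table(tab)
}

#' Validate an area table
#'
#' Checks the area-table contract: required columns present, counts
#' non-negative integers, populations strictly positive, covariate columns
#' numeric and complete, `area_id` unique, and (when an `expected` column is
#' present) total expected equal to total observed to within 1e-9 relative
#' (internal standardization).
#'
#' @param tab A data frame.
#' @return The table as a tibble, invisibly unchanged apart from class.
#' @export
validate_area_table <- function(tab) {
  tab <- tibble::as_tibble(tab)
  for (col in c("area_id", "observed", "population")) {
    if (!col %in% names(tab))
      stop("area table is missing required column '", col, "'")
  }
  if (anyDuplicated(tab$area_id))
    stop("duplicate area_id: ",
         paste(unique(tab$area_id[duplicated(tab$area_id)]), collapse = ", "))
  bad <- which(is.na(tab$observed) | tab$observed < 0 |
                 tab$observed != round(tab$observed))
  if (length(bad))
    stop("observed counts must be non-negative integers; offending row(s): ",
         paste(head(bad, 5), collapse = ", "))
  bad <- which(is.na(tab$population) | tab$population <= 0)
  if (length(bad))
    stop("population must be positive; offending row(s): ",
         paste(head(bad, 5), collapse = ", "))
  covs <- setdiff(names(tab), RESERVED_COLS)
  for (cv in covs) {
    if (!is.numeric(tab[[cv]]))
      stop("covariate column '", cv, "' is not numeric")
    if (anyNA(tab[[cv]]))
      stop("covariate column '", cv, "' has missing cells")
  }
  if ("expected" %in% names(tab)) {
    if (any(is.na(tab$expected) | tab$expected <= 0))
      stop("expected counts must be positive when present")
    rel <- abs(sum(tab$expected) - sum(tab$observed)) /
      max(sum(tab$observed), 1)
    if (rel > 1e-9)
      stop("sum(expected) must equal sum(observed) (internal ",
           "standardization); relative discrepancy ", format(rel))
  }
  attr(tab, "covariates") <- covs
  tab
}

#' Covariate column names of an area table
#' @param tab An area table.
#' @return Character vector of covariate column names.
#' @export
area_covariates <- function(tab) {
  setdiff(names(tab), RESERVED_COLS)
}

#' Write an area table to CSV
#' @param tab An area table.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_area_table <- function(tab, path) {
  tab <- validate_area_table(tab)
  readr::write_csv(tab, path, progress = FALSE)
  invisible(path)
}

#' Expected counts by internal standardization
#'
#' Computes the expected event count of each area under the district-wide
#' average rate, `E_i = pop_i * sum(O) / sum(pop)`, and stores it in the
#' `expected` column. With this offset the model's per-area relative risk is
#' measured against the whole-district incidence (risk 1 = district average),
#' and `sum(E) == sum(O)` by construction.
#'
#' @param tab An area table.
#' @return The table with an `expected` column added (or replaced).
#' @export
compute_expected <- function(tab) {
  tab <- validate_area_table(tab[setdiff(names(tab), "expected")])
  if (sum(tab$observed) == 0)
    stop("all observed counts are zero: the district rate is undefined")
  rate <- sum(tab$observed) / sum(tab$population)
  validate_area_table(dplyr::mutate(tab, expected = .data$population * rate))
}

#' Raw event rates per 1,000 population
#'
#' @param tab An area table.
#' @return Tibble with `area_id`, `observed`, `population` and `rate`
#'   (events per 1,000 population at risk).
#' @export
raw_rates <- function(tab) {
  tab <- validate_area_table(tab)
  dplyr::transmute(tab, area_id = .data$area_id, observed = .data$observed,
                   population = .data$population,
                   rate = 1000 * .data$observed / .data$population)
}
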