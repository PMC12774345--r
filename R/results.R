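# Reader for deposited regional index results (the published per-region
# score table), used for integration checks against printed summary
# statistics. The deposited workbook is access-controlled alongside the
# restricted microdata; export its regional sheet to CSV before loading.

#' Read a deposited regional results table
#'
#' Expects a CSV with one row per region: `region`, `country`, the eleven
#' indicator score columns (named `ind1` ... `ind11`, or any columns
#' matching `^ind`), and `pi`. Used to recompute summary statistics
#' (median regional index, country extremes, reliability, inequality
#' decomposition) from published results rather than restricted microdata.
#'
#' @param path CSV path.
#' @return Tibble with `region`, `country`, score columns, `pi`.
#' @export
read_regional_results <- function(path) {
  if (!file.exists(path)) {
    stop("deposited regional results not found at '", path,
         "'; export the published regional score table to CSV and pass ",
         "its path", call. = FALSE)
  }
  res <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  need <- c("region", "country", "pi")
  miss <- setdiff(need, names(res))
  if (length(miss) > 0) {
    stop("regional results lack column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  res
}

#' Summary statistics of a regional results table
#'
#' Median regional index, per-country means with their extremes, the
#' Theil decomposition of the index over countries, and lambda-6 over the
#' indicator score columns (when present).
#'
#' @param results Tibble from [read_regional_results()].
#' @return List with `median_pi`, `country_pi` (tibble), `max_country_pi`,
#'   `min_country_pi`, `theil`, `lambda6` (or `NULL`).
#' @export
summarize_regional_results <- function(results) {
  ok <- !is.na(results$pi)
  med <- stats::median(results$pi[ok])
  by_country <- results[ok, ] |>
    dplyr::group_by(.data$country) |>
    dplyr::summarise(pi = mean(.data$pi), n = dplyr::n(), .groups = "drop")
  theil <- if (dplyr::n_distinct(results$country[ok]) >= 2 &&
               all(results$pi[ok] > 0)) {
    theil_decomposition(results$pi[ok], results$country[ok])
  } else NULL
  ind_cols <- grep("^ind", names(results), value = TRUE)
  l6 <- if (length(ind_cols) >= 2) {
    guttman_lambda6(as.matrix(results[ok, ind_cols]))$lambda6
  } else NULL
  list(median_pi = med, country_pi = by_country,
       max_country_pi = max(by_country$pi),
       min_country_pi = min(by_country$pi),
       theil = theil, lambda6 = l6)
}
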