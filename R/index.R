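# Rescaling raw indicators to 0-10 scores and aggregating the nested
# average: four equally weighted domain sub-indices, summed to the 0-40
# overall index.

#' Direction-adjusted patriarchal intensity of a raw indicator value
#'
#' Makes every indicator point the same way, so that a higher value always
#' means a more patriarchal configuration: positive-direction indicators
#' pass through unchanged; negative-direction proportions are
#' complemented (`1 - raw`). Missing values propagate.
#'
#' @param raw Numeric vector of raw (or standardized) indicator values.
#' @param spec One-row registry spec, or an indicator id.
#' @return Numeric vector of intensities.
#' @export
#' @examples
#' patriarchal_intensity(0.2, 1)  # 20% female heads -> intensity 0.8
patriarchal_intensity <- function(raw, spec) {
  if (!is.data.frame(spec)) {
    spec <- indicator_registry()[indicator_registry()$id == spec, ]
  }
  if (spec$direction == "+") raw else 1 - raw
}

#' Scale intensities across regions to a 0-10 score
#'
#' `score = 10 * (intensity - m) / (B - m)` with `m` the indicator's
#' natural minimum and `B` the benchmark: the maximum intensity observed
#' across the supplied regions (default) or a fixed value. The region at
#' the benchmark scores exactly 10 and a region at the natural minimum 0;
#' intensities below the minimum clamp to 0. If no region rises above the
#' floor (`B = m`) every score is 0.
#'
#' @param intensities Named or unnamed numeric vector, one entry per
#'   region (`NA` = missing).
#' @param spec One-row registry spec or indicator id (supplies the natural
#'   minimum).
#' @param benchmark Optional fixed benchmark overriding the observed
#'   maximum; must strictly exceed the natural minimum.
#' @return Numeric vector of scores in `[0, 10]` (missing stays `NA`).
#' @export
#' @examples
#' scale_indicator(c(0, 0.2, 0.4), 2)  # 0, 5, 10
scale_indicator <- function(intensities, spec, benchmark = NULL) {
  if (!is.data.frame(spec)) {
    spec <- indicator_registry()[indicator_registry()$id == spec, ]
  }
  m <- spec$natural_min
  if (all(is.na(intensities))) return(intensities)
  B <- if (is.null(benchmark)) max(intensities, na.rm = TRUE) else benchmark
  if (!is.null(benchmark) && benchmark <= m) {
    stop("fixed benchmark must strictly exceed the natural minimum ", m,
         call. = FALSE)
  }
  if (B <= m) return(ifelse(is.na(intensities), NA_real_, 0))
  pmin(10, pmax(0, 10 * (intensities - m) / (B - m)))
}

#' Assemble domain sub-indices and the overall index from scores
#'
#' Each domain score is the unweighted mean of its member indicators'
#' 0-10 scores over non-missing members; the overall index is the sum of
#' the four domain scores (0-40). A domain with every member missing makes
#' the region's index missing, and all exclusions are logged.
#'
#' @param scores Tibble with columns `region`, `id`, `score`.
#' @return Tibble with one row per region: four domain columns, `pi`
#'   (0-40), `n_missing` and `missing_ids` (comma-separated log).
#' @export
assemble_pi <- function(scores) {
  dm <- domain_map()
  reg <- indicator_registry()
  scores <- dplyr::left_join(scores, reg[, c("id", "domain")], by = "id")
  dom <- scores |>
    dplyr::group_by(.data$region, .data$domain) |>
    dplyr::summarise(
      score = if (all(is.na(.data$score))) NA_real_
              else mean(.data$score, na.rm = TRUE),
      .groups = "drop")
  log <- scores |>
    dplyr::group_by(.data$region) |>
    dplyr::summarise(
      n_missing = sum(is.na(.data$score)),
      missing_ids = paste(.data$id[is.na(.data$score)], collapse = ","),
      .groups = "drop")
  wide <- tidyr::pivot_wider(dom, names_from = "domain",
                             values_from = "score")
  for (d in names(dm)) if (!d %in% names(wide)) wide[[d]] <- NA_real_
  wide$pi <- wide$male_domination + wide$generational_domination +
    wide$patrilocality + wide$son_preference
  dplyr::left_join(wide, log, by = "region")[
    , c("region", names(dm), "pi", "n_missing", "missing_ids")]
}

#' Compute the full index from a microdata table
#'
#' End-to-end driver: indicator matrix (with optional age-sex
#' standardization), direction adjustment, 0-10 scaling against the
#' supplied region set, and nested aggregation. Benchmarks are relative to
#' the regions present in `table` (run the same pipeline on country-level
#' partitions, via `level = "country"`, to obtain country indices — they
#' are not averages of regional ones).
#'
#' @param table Validated microdata tibble.
#' @param standardize Age-sex standardize indicators 1-9 (default `TRUE`)?
#' @param level `"region"` (default) or `"country"`: the benchmarking units.
#' @param adult_age Adulthood threshold for the kinship layer.
#' @return List with `pi` (per-unit result tibble), `scores` (long tibble
#'   region x indicator with raw, value, intensity, score), `benchmarks`
#'   (per-indicator benchmark metadata), and `std` (the structure used, or
#'   `NULL`).
#' @export
compute_pi <- function(table, standardize = TRUE, level = c("region", "country"),
                       adult_age = 18) {
  level <- match.arg(level)
  p <- tibble::as_tibble(table)
  if (level == "country") p$region <- p$country
  std <- if (standardize) compute_standard_structure(p) else NULL
  mat <- compute_indicator_matrix(p, std = std, adult_age = adult_age)
  reg <- indicator_registry()
  out <- list()
  bench <- list()
  for (k in seq_len(nrow(reg))) {
    spec <- reg[k, ]
    rows <- mat[mat$id == spec$id, ]
    intensity <- patriarchal_intensity(rows$value, spec)
    score <- scale_indicator(intensity, spec)
    B <- if (all(is.na(intensity))) NA_real_ else max(intensity, na.rm = TRUE)
    bench[[k]] <- tibble::tibble(id = spec$id, name = spec$name,
                                 natural_min = spec$natural_min,
                                 benchmark = B)
    rows$intensity <- intensity
    rows$score <- score
    out[[k]] <- rows
  }
  scores <- dplyr::bind_rows(out)
  list(pi = assemble_pi(scores[, c("region", "id", "score")]),
       scores = scores, benchmarks = dplyr::bind_rows(bench), std = std)
}
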