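# Region-level outcome measures computed from the microdata themselves:
# relative female labor force participation and the total modified
# Whipple age-heaping index with its female/male ratio.

#' Relative female labor force participation
#'
#' Weighted count of women in the labor force divided by the weighted
#' count of men in the labor force, per region. Regions with an empty male
#' labor force are flagged missing.
#'
#' @param table Microdata tibble.
#' @return Tibble (`region`, `flfp_rel`, `missing`).
#' @export
relative_flfp <- function(table) {
  p <- tibble::as_tibble(table)
  p |>
    dplyr::filter(.data$in_labor_force == "yes",
                  .data$sex %in% c("male", "female")) |>
    dplyr::group_by(.data$region) |>
    dplyr::summarise(
      w_f = sum(.data$weight[.data$sex == "female"]),
      w_m = sum(.data$weight[.data$sex == "male"]), .groups = "drop") |>
    dplyr::mutate(flfp_rel = ifelse(.data$w_m > 0, .data$w_f / .data$w_m,
                                    NA_real_),
                  missing = .data$w_m == 0) |>
    dplyr::select("region", "flfp_rel", "missing")
}

#' Total modified Whipple age-heaping index
#'
#' Measures digit preference in reported ages over all ten terminal
#' digits: for each digit `d`, `W_d = 10 * (weighted persons in range
#' whose age ends in d) / (weighted persons in range)`, and
#' `W_tot = sum_d |W_d - 1|`. 0 means no heaping; 18 is total
#' concentration on a single digit. The default age window 23-62 covers
#' four full decades so every terminal digit appears exactly four times.
#' Persons with unknown age are excluded and counted.
#'
#' @param ages Integer ages.
#' @param weights Optional non-negative weights (default 1).
#' @param range Inclusive age window, default `c(23, 62)`.
#' @return List with `w_tot`, `digit_table` (per-digit W_d),
#'   `n_excluded_unknown_age`, `missing` (TRUE when no one is in range).
#' @export
whipple_total <- function(ages, weights = NULL, range = c(23, 62)) {
  w <- if (is.null(weights)) rep(1, length(ages)) else weights
  unknown <- is.na(ages)
  keep <- !unknown & ages >= range[1] & ages <= range[2]
  if (!any(keep)) {
    return(list(w_tot = NA_real_, digit_table = NULL,
                n_excluded_unknown_age = sum(unknown), missing = TRUE))
  }
  a <- ages[keep]; wk <- w[keep]
  digit <- a %% 10
  wd <- vapply(0:9, function(d) sum(wk[digit == d]), numeric(1))
  wd <- 10 * wd / sum(wk)
  list(w_tot = sum(abs(wd - 1)),
       digit_table = tibble::tibble(digit = 0:9, W_d = wd),
       n_excluded_unknown_age = sum(unknown), missing = FALSE)
}

#' Region-level outcome table
#'
#' Computes, per region, relative female labor force participation and the
#' total modified Whipple index by sex with its female/male ratio.
#'
#' @param table Microdata tibble.
#' @param whipple_range Age window for the Whipple index.
#' @return Tibble (`region`, `flfp_rel`, `wtot_female`, `wtot_male`,
#'   `wtot_ratio`).
#' @export
compute_outcomes <- function(table, whipple_range = c(23, 62)) {
  p <- tibble::as_tibble(table)
  flfp <- relative_flfp(p)
  wt <- p |>
    dplyr::filter(.data$sex %in% c("male", "female")) |>
    dplyr::group_by(.data$region) |>
    dplyr::summarise(
      wtot_female = whipple_total(.data$age[.data$sex == "female"],
                                  .data$weight[.data$sex == "female"],
                                  whipple_range)$w_tot,
      wtot_male = whipple_total(.data$age[.data$sex == "male"],
                                .data$weight[.data$sex == "male"],
                                whipple_range)$w_tot,
      .groups = "drop") |>
    dplyr::mutate(wtot_ratio = .data$wtot_female / .data$wtot_male)
  dplyr::left_join(flfp[, c("region", "flfp_rel")], wt, by = "region")
}
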