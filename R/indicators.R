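# The eleven raw indicators, computed per region with direct age-sex
# standardization for the rate-type indicators (1-9). Indicators 10-11 are
# sex-composition measures and stay crude.

#' The shipped indicator registry
#'
#' One row per indicator: its domain, direction of association with
#' patriarchy (`"+"`: higher value = more patriarchal; `"-"`: the
#' complement is taken before scaling), the age band of its reference
#' population, whether it is age-standardized and over which cells
#' (`std_sex`: `"female"`, `"male"`, `"both"` for age-by-sex cells,
#' `"age_only"` where sex is the outcome, `"none"`), and the natural
#' minimum used in scaling (0 after direction adjustment for 1-9; the
#' neutral boys' proportion 0.51 for 10; the neutral under-five sex ratio
#' 105 for 11).
#'
#' @return Tibble with 11 rows.
#' @export
indicator_registry <- function() {
  tibble::tribble(
    ~id, ~name,                      ~domain,          ~direction, ~standardize, ~std_sex,   ~age_lo, ~age_hi, ~natural_min,
    1L, "female_heads",              "male_domination",        "-", TRUE,  "age_only", 20L, 130L, 0,
    2L, "teen_married_women",        "male_domination",        "+", TRUE,  "female",   15L, 19L,  0,
    3L, "wife_older_couples",        "male_domination",        "-", TRUE,  "female",   0L,  130L, 0,
    4L, "young_women_nonkin",        "male_domination",        "-", TRUE,  "female",   20L, 24L,  0,
    5L, "elder_men_younger_head",    "generational_domination","-", TRUE,  "male",     65L, 130L, 0,
    6L, "young_male_neolocal",       "generational_domination","-", TRUE,  "male",     20L, 29L,  0,
    7L, "elders_with_lateral_kin",   "generational_domination","+", TRUE,  "both",     65L, 130L, 0,
    8L, "elders_alone",              "generational_domination","-", TRUE,  "both",     65L, 130L, 0,
    9L, "wives_with_husbands_kin",   "patrilocality",          "+", TRUE,  "female",   15L, 30L,  0,
    10L, "boys_10_14",               "son_preference",         "+", FALSE, "none",     10L, 14L,  0.51,
    11L, "sex_ratio_0_4",            "son_preference",         "+", FALSE, "none",     0L,  4L,   105
  )
}

#' The four domains and their member indicators
#' @return Named list of integer indicator ids per domain.
#' @export
domain_map <- function() {
  list(male_domination = 1:4, generational_domination = 5:8,
       patrilocality = 9L, son_preference = 10:11)
}

age_bin <- function(age) 5L * (as.integer(age) %/% 5L)

#' Average age-sex structure of a set of national populations
#'
#' The weighted (5-year age bin x sex) distribution is computed within each
#' country, the unweighted arithmetic mean of the country distributions is
#' taken, and the result renormalized. Persons with unknown age or sex are
#' excluded.
#'
#' @param table Microdata tibble covering one or more countries (or a list
#'   of tables, which are concatenated).
#' @return Tibble (`age_bin`, `sex`, `share`) with shares summing to 1.
#' @export
compute_standard_structure <- function(table) {
  if (is.list(table) && !is.data.frame(table)) {
    table <- dplyr::bind_rows(lapply(table, tibble::as_tibble))
  }
  p <- tibble::as_tibble(table) |>
    dplyr::filter(!is.na(.data$age), .data$sex %in% c("male", "female"))
  if (nrow(p) == 0) stop("no persons with known age and sex", call. = FALSE)
  per_country <- p |>
    dplyr::mutate(age_bin = age_bin(.data$age)) |>
    dplyr::group_by(.data$country, .data$age_bin, .data$sex) |>
    dplyr::summarise(w = sum(.data$weight), .groups = "drop_last") |>
    dplyr::group_by(.data$country) |>
    dplyr::mutate(share = .data$w / sum(.data$w)) |>
    dplyr::ungroup()
  n_countries <- dplyr::n_distinct(per_country$country)
  std <- per_country |>
    dplyr::group_by(.data$age_bin, .data$sex) |>
    dplyr::summarise(share = sum(.data$share) / n_countries,
                     .groups = "drop")
  std$share <- std$share / sum(std$share)
  std
}

# Unit-level observations for one indicator: one row per member of the
# denominator, with the numerator membership flag and the reference
# age/sex used for standardization cells.
indicator_units <- function(table, id, adult_age = 18) {
  p <- tibble::as_tibble(table)
  ever <- c("married_in_union", "separated_divorced", "widowed")
  unit <- function(df, num) {
    tibble::tibble(region = df$region, age_ref = df$age, sex_ref = df$sex,
                   weight = df$weight, num = num)
  }
  known <- !is.na(p$age)
  if (id == 1L) {
    d <- p[p$relate == "head" & known & p$age >= 20, ]
    return(unit(d, d$sex == "female"))
  }
  if (id == 2L) {
    d <- p[p$sex == "female" & known & p$age >= 15 & p$age <= 19, ]
    return(unit(d, d$marital_status %in% ever))
  }
  if (id == 3L) {
    cps <- identify_couples(p)$couples
    cps <- cps[!is.na(cps$husband_age) & !is.na(cps$wife_age), ]
    hh_region <- p$region[match(cps$household_id, p$household_id)]
    return(tibble::tibble(region = hh_region, age_ref = cps$wife_age,
                          sex_ref = "female", weight = cps$weight,
                          num = cps$wife_age > cps$husband_age))
  }
  if (id == 4L) {
    nk <- lives_without_relatives(p)
    keep <- p$sex == "female" & known & p$age >= 20 & p$age <= 24
    return(unit(p[keep, ], nk[keep]))
  }
  if (id == 5L) {
    heads <- p[p$relate == "head", ]
    i <- match(p$household_id, heads$household_id)
    kc <- kin_class(p$relate)
    younger_male_head <- !is.na(i) & heads$sex[i] == "male" &
      !is.na(heads$age[i]) & !is.na(p$age) & heads$age[i] < p$age &
      kc %in% c("direct_kin", "lateral_kin")
    keep <- p$sex == "male" & known & p$age >= 65
    return(unit(p[keep, ], younger_male_head[keep]))
  }
  if (id == 6L) {
    imm <- p |>
      dplyr::group_by(.data$household_id) |>
      dplyr::summarise(
        immediate_only = all(.data$relate %in% c("head", "spouse", "child")),
        .groups = "drop")
    i <- match(p$household_id, imm$household_id)
    neolocal <- p$relate == "head" & imm$immediate_only[i]
    keep <- p$sex == "male" & known & p$age >= 20 & p$age <= 29
    return(unit(p[keep, ], neolocal[keep]))
  }
  if (id == 7L) {
    lat <- has_lateral_kin(p)
    keep <- known & p$age >= 65
    return(unit(p[keep, ], lat[keep]))
  }
  if (id == 8L) {
    alone <- lives_without_relatives(p)
    keep <- known & p$age >= 65
    return(unit(p[keep, ], alone[keep]))
  }
  if (id == 9L) {
    hk <- has_husbands_kin(p, adult_age = adult_age)
    j <- match(paste(p$household_id, p$person_number),
               paste(hk$household_id, hk$person_number))
    verdict <- hk$husbands_kin[j]
    keep <- p$sex == "female" & known & p$age >= 15 & p$age <= 30 &
      !is.na(verdict) & verdict != "indeterminate"
    return(unit(p[keep, ], verdict[keep] == "yes"))
  }
  if (id == 10L) {
    d <- p[known & p$age >= 10 & p$age <= 14 &
             p$sex %in% c("male", "female"), ]
    return(unit(d, d$sex == "male"))
  }
  if (id == 11L) {
    d <- p[known & p$age <= 4 & p$sex %in% c("male", "female"), ]
    return(unit(d, d$sex == "male"))
  }
  stop("unknown indicator id: ", id, call. = FALSE)
}

# Weighted crude and standardized values for one indicator over the
# units of one region.
aggregate_units <- function(u, spec, std) {
  denom <- sum(u$weight)
  if (denom == 0 || nrow(u) == 0) {
    return(list(raw = NA_real_, value = NA_real_, denom = 0, missing = TRUE))
  }
  if (spec$id == 11L) {
    boys <- sum(u$weight[u$num]); girls <- sum(u$weight[!u$num])
    if (girls == 0) {
      return(list(raw = NA_real_, value = NA_real_, denom = denom,
                  missing = TRUE))
    }
    raw <- 100 * boys / girls
    return(list(raw = raw, value = raw, denom = denom, missing = FALSE))
  }
  raw <- sum(u$weight * u$num) / denom
  value <- raw
  if (isTRUE(spec$standardize) && !is.null(std)) {
    # cell = 5-year bin of the reference age, by sex unless sex is the
    # outcome (std_sex "age_only") in which case sexes are pooled
    uc <- dplyr::mutate(u, age_bin = age_bin(.data$age_ref),
                        sex = if (spec$std_sex == "age_only") "any"
                              else .data$sex_ref)
    cells <- uc |>
      dplyr::group_by(.data$age_bin, .data$sex) |>
      dplyr::summarise(rate = sum(.data$weight * .data$num) / sum(.data$weight),
                       .groups = "drop")
    w <- std |>
      dplyr::filter(.data$age_bin >= age_bin(spec$age_lo),
                    .data$age_bin <= spec$age_hi)
    if (spec$std_sex %in% c("female", "male")) {
      w <- dplyr::filter(w, .data$sex == spec$std_sex)
    } else if (spec$std_sex == "age_only") {
      w <- w |>
        dplyr::group_by(.data$age_bin) |>
        dplyr::summarise(share = sum(.data$share), .groups = "drop") |>
        dplyr::mutate(sex = "any")
    }
    joined <- dplyr::inner_join(cells, w, by = c("age_bin", "sex"))
    if (nrow(joined) > 0 && sum(joined$share) > 0) {
      value <- sum(joined$rate * joined$share) / sum(joined$share)
    }
  }
  list(raw = raw, value = value, denom = denom, missing = FALSE)
}

#' Compute one raw (and standardized) indicator for one region
#'
#' Weighted proportions for indicators 1-10 and 100 x boys/girls for
#' indicator 11, per the shipped registry. When the indicator is
#' standardized, the value is the standard-structure-weighted average of
#' 5-year-cell rates over the indicator's band, restricted to cells with
#' non-empty regional denominators (weights renormalized).
#'
#' @param table Microdata tibble.
#' @param region Region code.
#' @param id Indicator id (1-11) or a one-row registry spec.
#' @param std Age-sex structure from [compute_standard_structure()], or
#'   `NULL` for crude values.
#' @param adult_age Adulthood threshold passed to the kinship layer.
#' @return List with `raw`, `value` (standardized where applicable),
#'   `denom` (weighted denominator size), `missing`.
#' @export
compute_raw_indicator <- function(table, region, id, std = NULL,
                                  adult_age = 18) {
  spec <- if (is.data.frame(id)) id else
    indicator_registry()[indicator_registry()$id == id, ]
  p <- tibble::as_tibble(table)
  if (!region %in% p$region) stop("region not in table: ", region,
                                  call. = FALSE)
  u <- indicator_units(p[p$region == region, ], spec$id,
                       adult_age = adult_age)
  aggregate_units(u, spec, std)
}

#' Compute the full region-by-indicator matrix
#'
#' Batch driver applying all eleven indicators to every region of a
#' validated table. Equals cell-wise calls of [compute_raw_indicator()].
#'
#' @inheritParams compute_raw_indicator
#' @return Tibble with one row per (region, indicator): `region`, `id`,
#'   `name`, `domain`, `raw`, `value`, `denom`, `missing`.
#' @export
compute_indicator_matrix <- function(table, std = NULL, adult_age = 18) {
  p <- tibble::as_tibble(table)
  regions <- sort(unique(p$region))
  reg <- indicator_registry()
  rows <- list()
  for (k in seq_len(nrow(reg))) {
    spec <- reg[k, ]
    units <- indicator_units(p, spec$id, adult_age = adult_age)
    for (r in regions) {
      a <- aggregate_units(units[units$region == r, ], spec, std)
      rows[[length(rows) + 1]] <- tibble::tibble(
        region = r, id = spec$id, name = spec$name, domain = spec$domain,
        raw = a$raw, value = a$value, denom = a$denom, missing = a$missing)
    }
  }
  dplyr::bind_rows(rows) |> dplyr::arrange(.data$region, .data$id)
}
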