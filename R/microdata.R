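# Person-level microdata container and delimited-text readers/writers.
#
# A microdata table is a tibble of person records, one row per person,
# grouped into households by `household_id`. Mandatory columns:
#   household_id (chr), person_number (int, unique within household),
#   region (chr), country (chr), weight (dbl >= 0), age (int, NA = unknown),
#   sex, marital_status, relate, urban, in_labor_force (harmonized strings),
#   spouse_loc, mother_loc, father_loc (int person_number or NA).
# Provenance (source name, enumeration year) travels in attributes.

microdata_cols <- c(
  "household_id", "person_number", "region", "country", "weight", "age",
  "sex", "marital_status", "relate", "spouse_loc", "mother_loc",
  "father_loc", "urban", "in_labor_force"
)

mandatory_roles <- c("household_id", "person_number", "region", "country",
                     "age", "sex", "marital_status", "relate")

#' Construct a microdata table from a data frame of harmonized person records
#'
#' Validates column presence and types, fills optional columns with their
#' defaults (weight 1, locators `NA`, urban/labor-force `"unknown"`), and
#' checks the structural invariants: unique `(household_id, person_number)`
#' keys, non-negative weights, every region mapping to exactly one country.
#'
#' @param persons Data frame with at least the mandatory columns.
#' @param source,year Optional provenance metadata stored as attributes.
#' @return A tibble of person records with class `"microdata_tbl"`.
#' @export
as_microdata <- function(persons, source = NA_character_, year = NA_integer_) {
  persons <- tibble::as_tibble(persons)
  missing_cols <- setdiff(mandatory_roles, names(persons))
  if (length(missing_cols) > 0) {
    stop("microdata is missing mandatory column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (!"weight" %in% names(persons)) persons$weight <- 1
  for (loc in c("spouse_loc", "mother_loc", "father_loc")) {
    if (!loc %in% names(persons)) persons[[loc]] <- NA_integer_
    persons[[loc]] <- as.integer(persons[[loc]])
  }
  for (cat in c("urban", "in_labor_force")) {
    if (!cat %in% names(persons)) persons[[cat]] <- "unknown"
  }
  persons <- dplyr::mutate(
    persons,
    household_id = as.character(.data$household_id),
    person_number = as.integer(.data$person_number),
    region = as.character(.data$region),
    country = as.character(.data$country),
    weight = as.numeric(.data$weight),
    age = as.integer(.data$age)
  )
  persons <- persons[, microdata_cols]

  dup <- persons |>
    dplyr::count(.data$household_id, .data$person_number) |>
    dplyr::filter(.data$n > 1)
  if (nrow(dup) > 0) {
    keys <- paste0("(", dup$household_id, ", ", dup$person_number, ")")
    stop("duplicate (household_id, person_number) key(s): ",
         paste(utils::head(keys, 10), collapse = ", "), call. = FALSE)
  }
  if (any(persons$weight < 0, na.rm = TRUE)) {
    stop("person weights must be non-negative", call. = FALSE)
  }
  rc <- persons |>
    dplyr::distinct(.data$region, .data$country) |>
    dplyr::count(.data$region) |>
    dplyr::filter(.data$n > 1)
  if (nrow(rc) > 0) {
    stop("region(s) mapped to more than one country: ",
         paste(rc$region, collapse = ", "), call. = FALSE)
  }
  bad_age <- persons$age[!is.na(persons$age)]
  if (any(bad_age < 0 | bad_age > 130)) {
    stop("ages must lie in 0-130 years (use NA for unknown)", call. = FALSE)
  }
  structure(persons,
            class = c("microdata_tbl", class(persons)),
            provenance = list(source = source, year = year))
}

#' Read person-level microdata from a delimited text file
#'
#' Reads a comma-separated, UTF-8, headered person file and harmonizes its
#' codes. `varmap` names, for each variable role, the column that carries it
#' (roles: `household_id`, `person_number`, `region`, `country`, `age`,
#' `sex`, `marital_status`, `relate` mandatory; `weight`, `spouse_loc`,
#' `mother_loc`, `father_loc`, `urban`, `in_labor_force` optional). Raw
#' categorical codes are translated via `code_maps` (see
#' [default_code_maps()]); unmappable codes become `"unknown"` and are
#' counted per variable in the load report. An absent weight role yields a
#' self-weighting sample (weight 1).
#'
#' @param path Path to the CSV file.
#' @param varmap Named list/character vector: role -> column name. May also
#'   be a path to a JSON or YAML configuration file with fields `varmap`
#'   and optionally `code_maps`.
#' @param code_maps Raw-to-harmonized code tables; defaults to
#'   [default_code_maps()].
#' @param source,year Provenance metadata.
#' @return A list with elements `table` (a microdata tibble) and `report`
#'   (named list: rows read, unmappable-code counts per variable).
#' @export
read_microdata <- function(path, varmap, code_maps = default_code_maps(),
                           source = basename(path), year = NA_integer_) {
  if (is.character(varmap) && length(varmap) == 1 && file.exists(varmap)) {
    cfg <- read_config(varmap)
    if (!is.null(cfg$code_maps)) code_maps <- merge_code_maps(cfg$code_maps)
    varmap <- cfg$varmap
  }
  varmap <- unlist(varmap)
  missing_roles <- setdiff(mandatory_roles, names(varmap))
  if (length(missing_roles) > 0) {
    stop("varmap does not name mandatory role(s): ",
         paste(missing_roles, collapse = ", "), call. = FALSE)
  }
  raw <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE,
                         col_types = readr::cols(.default = readr::col_character()))
  missing_cols <- setdiff(unname(varmap), names(raw))
  if (length(missing_cols) > 0) {
    stop("input file lacks column(s) named by varmap: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }

  persons <- tibble::tibble(
    household_id = raw[[varmap[["household_id"]]]],
    person_number = suppressWarnings(as.integer(raw[[varmap[["person_number"]]]])),
    region = raw[[varmap[["region"]]]],
    country = raw[[varmap[["country"]]]],
    age = suppressWarnings(as.integer(raw[[varmap[["age"]]]]))
  )
  persons$age[!is.na(persons$age) & (persons$age < 0 | persons$age > 130)] <- NA_integer_
  persons$weight <- if ("weight" %in% names(varmap)) {
    suppressWarnings(as.numeric(raw[[varmap[["weight"]]]]))
  } else 1
  for (loc in c("spouse_loc", "mother_loc", "father_loc")) {
    persons[[loc]] <- if (loc %in% names(varmap)) {
      suppressWarnings(as.integer(raw[[varmap[[loc]]]]))
    } else NA_integer_
  }

  unmapped <- list()
  recode <- function(role) {
    if (!role %in% names(varmap)) return(rep("unknown", nrow(raw)))
    codes <- raw[[varmap[[role]]]]
    map <- code_maps[[role]]
    out <- unname(map[codes])
    # codes already given as harmonized level strings pass through unchanged
    lv <- switch(role, relate = relate_levels, sex = sex_levels,
                 marital_status = marst_levels, urban = urban_levels,
                 in_labor_force = labforce_levels)
    pass <- is.na(out) & codes %in% lv
    out[pass] <- codes[pass]
    unmapped[[role]] <<- sum(is.na(out) & !is.na(codes))
    out[is.na(out)] <- "unknown"
    out
  }
  persons$sex <- recode("sex")
  persons$marital_status <- recode("marital_status")
  persons$relate <- recode("relate")
  persons$urban <- recode("urban")
  persons$in_labor_force <- recode("in_labor_force")

  table <- as_microdata(persons, source = source, year = year)
  list(table = table,
       report = list(rows = nrow(table), unmapped_codes = unmapped))
}

merge_code_maps <- function(user) {
  maps <- default_code_maps()
  for (nm in names(user)) maps[[nm]] <- unlist(user[[nm]])
  maps
}

read_config <- function(path) {
  if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::read_yaml(path)
  } else {
    # keep arrays-of-objects (e.g. scenario lists) as lists, not frames
    jsonlite::read_json(path, simplifyVector = TRUE,
                        simplifyDataFrame = FALSE)
  }
}

#' Write a harmonized microdata table to CSV
#'
#' Inverse of [read_microdata()] for already-harmonized tables: the written
#' file uses the package's column names and harmonized level strings, so
#' `read_microdata(path, varmap = identity_varmap())` round-trips exactly.
#'
#' @param table Microdata tibble.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_microdata <- function(table, path) {
  readr::write_csv(tibble::as_tibble(table)[, microdata_cols], path,
                   progress = FALSE)
  invisible(path)
}

#' Identity variable map for files written by [write_microdata()]
#' @return Named character vector mapping every role to its own name.
#' @export
identity_varmap <- function() stats::setNames(microdata_cols, microdata_cols)

#' Read a region-level covariate table
#'
#' Reads a CSV keyed by `region` with any of the columns `gni_log`
#' (log GNI per capita, thousands USD 2011 PPP), `pct_urban` (proportion,
#' 0-1), and outcome measures `flfp_rel`, `eys_ratio`, `wtot_ratio`,
#' `cgfr`, `e0_gap` (dimensionless ratios).
#'
#' @param path CSV path.
#' @return Tibble keyed by region.
#' @export
read_covariates <- function(path) {
  cov <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  if (!"region" %in% names(cov)) {
    stop("covariate table must have a 'region' column", call. = FALSE)
  }
  cov$region <- as.character(cov$region)
  if ("pct_urban" %in% names(cov)) {
    pu <- cov$pct_urban
    if (any(pu < 0 | pu > 1, na.rm = TRUE)) {
      stop("pct_urban must lie in [0, 1]", call. = FALSE)
    }
  }
  cov
}

#' Repair household-level anomalies
#'
#' Resolves households with zero or multiple designated heads and
#' asymmetric spouse pointers. All problems are repaired and counted, never
#' fatal. Under the default `"drop"` policy a household without exactly one
#' head is removed (every indicator references headship, so imputing a head
#' would bias them); under `"oldest_male"` the oldest male (falling back to
#' the oldest member) is recoded as head and any surplus heads to
#' `"other_relative"`. A spouse pointer `A -> B` with `B`'s pointer null is
#' symmetrized when `B` points at nobody else; contradictory pointers are
#' nulled. The operation is idempotent.
#'
#' @param table Microdata tibble.
#' @param policy `"drop"` (default) or `"oldest_male"`.
#' @return List with `table` (repaired microdata) and `report` (counts:
#'   `dropped`, `reheaded`, `repaired_spouse`, `nulled_spouse`).
#' @export
validate_households <- function(table, policy = c("drop", "oldest_male")) {
  policy <- match.arg(policy)
  persons <- tibble::as_tibble(table)
  prov <- attr(table, "provenance")

  heads <- persons |>
    dplyr::group_by(.data$household_id) |>
    dplyr::summarise(n_heads = sum(.data$relate == "head"), .groups = "drop")
  bad <- heads$household_id[heads$n_heads != 1]
  dropped <- 0L; reheaded <- 0L
  if (length(bad) > 0) {
    if (policy == "drop") {
      persons <- dplyr::filter(persons, !.data$household_id %in% bad)
      dropped <- length(bad)
    } else {
      fix_one <- function(df) {
        df$relate[df$relate == "head"] <- "other_relative"
        ord <- order(df$sex != "male", -ifelse(is.na(df$age), -1, df$age))
        df$relate[ord[1]] <- "head"
        df
      }
      in_bad <- persons$household_id %in% bad
      fixed <- persons[in_bad, ] |>
        dplyr::group_by(.data$household_id) |>
        dplyr::group_modify(~ fix_one(.x)) |>
        dplyr::ungroup()
      persons <- dplyr::bind_rows(persons[!in_bad, ], fixed)
      reheaded <- length(bad)
    }
  }

  # spouse-pointer symmetry
  repaired <- 0L; nulled <- 0L
  key <- paste(persons$household_id, persons$person_number)
  idx <- match(paste(persons$household_id, persons$spouse_loc), key)
  has_ptr <- !is.na(persons$spouse_loc)
  dangling <- has_ptr & is.na(idx)            # no such person
  persons$spouse_loc[dangling] <- NA_integer_
  nulled <- nulled + sum(dangling)
  idx <- match(paste(persons$household_id, persons$spouse_loc), key)
  back <- persons$spouse_loc[idx]             # partner's pointer
  asym <- !is.na(idx) & (is.na(back) | back != persons$person_number)
  polygamous <- 0L
  if (any(asym)) {
    n_claims <- table(idx[asym])  # how many people point at each partner
    for (i in which(asym)) {
      j <- idx[i]
      opposite <- persons$sex[i] %in% c("male", "female") &&
        persons$sex[j] %in% c("male", "female") &&
        persons$sex[i] != persons$sex[j]
      if (is.na(persons$spouse_loc[j]) &&
          n_claims[[as.character(j)]] == 1L) {
        # partner points at nobody and i is the unique claimant: symmetrize
        persons$spouse_loc[j] <- persons$person_number[i]
        repaired <- repaired + 1L
      } else if (opposite) {
        # several opposite-sex claimants (or a partner already paired):
        # a polygamous union; keep the one-way pointer, one couple per wife
        polygamous <- polygamous + 1L
      } else {
        persons$spouse_loc[i] <- NA_integer_
        nulled <- nulled + 1L
      }
    }
  }
  # parent locators must refer to existing members
  for (loc in c("mother_loc", "father_loc")) {
    pidx <- match(paste(persons$household_id, persons[[loc]]), key)
    gone <- !is.na(persons[[loc]]) & is.na(pidx)
    persons[[loc]][gone] <- NA_integer_
    nulled <- nulled + sum(gone)
  }

  out <- as_microdata(persons, source = prov$source, year = prov$year)
  list(table = out,
       report = list(dropped = dropped, reheaded = reheaded,
                     repaired_spouse = repaired, nulled_spouse = nulled,
                     polygamous_kept = polygamous))
}
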