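# Harmonized category levels and shipped default code maps.
#
# Internally every categorical field is stored as a lower-case string drawn
# from the level sets below. Readers translate raw file codes into these
# levels through a user-supplied (or shipped default) code map, so national
# recodings live entirely in configuration.

relate_levels <- c(
  "head", "spouse", "child", "child_in_law", "parent", "parent_in_law",
  "grandchild", "grandparent", "sibling", "sibling_in_law", "nephew_niece",
  "cousin", "aunt_uncle", "other_relative", "lodger", "employee",
  "other_nonrel", "unknown"
)

sex_levels     <- c("male", "female", "unknown")
marst_levels   <- c("never_married", "married_in_union", "separated_divorced",
                    "widowed", "unknown")
urban_levels   <- c("urban", "rural", "unknown")
labforce_levels <- c("yes", "no", "unknown")

#' Default raw-to-harmonized code maps
#'
#' A list of named character vectors translating numeric file codes into the
#' package's harmonized category levels. The shipped values approximate the
#' detailed relationship-to-head, marital-status, sex, urban and labor-force
#' categories of harmonized international census extracts; supply your own
#' map in the reader configuration whenever the source file uses a different
#' codebook. Codes absent from the map are harmonized to `"unknown"` and
#' counted in the load report.
#'
#' @return Named list with elements `relate`, `sex`, `marital_status`,
#'   `urban`, `in_labor_force`, each a named character vector
#'   (names = raw codes as character, values = harmonized levels).
#' @export
#' @examples
#' default_code_maps()$sex
default_code_maps <- function() {
  list(
    relate = c(
      "1000" = "head", "2000" = "spouse", "2100" = "spouse",
      "3000" = "child", "3100" = "child", "3200" = "child",
      "3300" = "child", "3400" = "child_in_law",
      "4100" = "parent", "4200" = "parent_in_law",
      "4400" = "grandchild", "4500" = "grandparent",
      "4810" = "sibling", "4820" = "sibling_in_law",
      "4830" = "nephew_niece", "4840" = "cousin", "4850" = "aunt_uncle",
      "4900" = "other_relative",
      "5100" = "lodger", "5200" = "employee", "5900" = "other_nonrel"
    ),
    sex = c("1" = "male", "2" = "female"),
    marital_status = c(
      "1" = "never_married", "2" = "married_in_union",
      "3" = "separated_divorced", "4" = "widowed"
    ),
    urban = c("1" = "rural", "2" = "urban"),
    in_labor_force = c("1" = "no", "2" = "yes")
  )
}

#' Classify a relationship-to-head code into a kin class
#'
#' Collapses the harmonized relationship categories into the five kin
#' classes the indicators operate on: the head, the head's spouse, direct
#' (lineal and in-marrying lineal) kin, lateral kin (relatives outside the
#' direct descent line), non-kin, and unknown.
#'
#' @param relate Character vector of harmonized relationship levels.
#' @param other_relative_lateral Should the residual `"other_relative"`
#'   category count as lateral kin (default `TRUE`)? The boundary between
#'   lateral and unclassifiable kin is a convention; see the methods
#'   vignette.
#' @return Character vector over `{head, spouse_of_head, direct_kin,
#'   lateral_kin, non_kin, unknown}`.
#' @export
#' @examples
#' kin_class(c("head", "sibling", "lodger", "grandchild"))
kin_class <- function(relate, other_relative_lateral = TRUE) {
  lateral <- c("sibling", "sibling_in_law", "nephew_niece", "cousin",
               "aunt_uncle", if (other_relative_lateral) "other_relative")
  direct <- c("child", "child_in_law", "parent", "parent_in_law",
              "grandchild", "grandparent",
              if (!other_relative_lateral) "other_relative")
  dplyr::case_when(
    relate == "head" ~ "head",
    relate == "spouse" ~ "spouse_of_head",
    relate %in% direct ~ "direct_kin",
    relate %in% lateral ~ "lateral_kin",
    relate %in% c("lodger", "employee", "other_nonrel") ~ "non_kin",
    .default = "unknown"
  )
}
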