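# Relational facts derived from relationship-to-head codes and the three
# within-household locators (spouse/mother/father person numbers).
#
# Census microdata encode each member's relationship to the household head
# only, so laterality and "husband's kin" are resolved from the head's
# perspective; for members other than the head and spouse this is an
# approximation (the exact chain to each member is unrecoverable from
# relate-to-head codes alone).

#' Identify co-resident couples within households
#'
#' One couple per spouse-pointer pair; a symmetric pair yields a single
#' couple, and one-way opposite-sex pointers (polygamous unions, where one
#' man is pointed to by several wives) yield one couple per wife. Where
#' pointers are absent entirely, `(head, spouse-of-head)` pairs are formed
#' from the relationship codes as a fallback. Same-sex or unresolvable
#' pairs are skipped and counted.
#'
#' @param table Validated microdata tibble (see [validate_households()]).
#' @return List with `couples`, a tibble
#'   (`household_id`, `husband_pn`, `wife_pn`, `husband_age`, `wife_age`,
#'   `wife_relate`, `weight` — the mean of the two member weights), and
#'   `skipped`, the count of unresolvable pairs.
#' @export
identify_couples <- function(table) {
  p <- tibble::as_tibble(table)
  key <- paste(p$household_id, p$person_number)
  idx <- match(paste(p$household_id, p$spouse_loc), key)

  has <- !is.na(idx)
  pairs <- tibble::tibble(
    household_id = p$household_id[has],
    a = which(has), b = idx[has]
  )
  # households where some pointer exists (fallback only where none do)
  ptr_hh <- unique(p$household_id[has])

  # head/spouse fallback pairs in pointerless households
  fb <- p |>
    dplyr::mutate(.row = dplyr::row_number()) |>
    dplyr::filter(!.data$household_id %in% ptr_hh,
                  .data$relate %in% c("head", "spouse"))
  fb_pairs <- NULL
  if (nrow(fb) > 0) {
    heads <- dplyr::filter(fb, .data$relate == "head")
    spouses <- dplyr::filter(fb, .data$relate == "spouse")
    j <- match(spouses$household_id, heads$household_id)
    ok <- !is.na(j)
    fb_pairs <- tibble::tibble(
      household_id = spouses$household_id[ok],
      a = spouses$.row[ok], b = heads$.row[j[ok]]
    )
  }
  pairs <- dplyr::bind_rows(pairs, fb_pairs)

  skipped <- 0L
  if (nrow(pairs) == 0) {
    return(list(couples = tibble::tibble(
      household_id = character(), husband_pn = integer(),
      wife_pn = integer(), husband_age = integer(), wife_age = integer(),
      wife_relate = character(), weight = numeric()), skipped = 0L))
  }

  sex_a <- p$sex[pairs$a]; sex_b <- p$sex[pairs$b]
  resolvable <- sex_a %in% c("male", "female") &
    sex_b %in% c("male", "female") & sex_a != sex_b
  skipped <- skipped + sum(!resolvable)
  pairs <- pairs[resolvable, ]
  wife <- ifelse(p$sex[pairs$a] == "female", pairs$a, pairs$b)
  husb <- ifelse(p$sex[pairs$a] == "female", pairs$b, pairs$a)
  couples <- tibble::tibble(
    household_id = pairs$household_id,
    husband_pn = p$person_number[husb], wife_pn = p$person_number[wife],
    husband_age = p$age[husb], wife_age = p$age[wife],
    wife_relate = p$relate[wife],
    weight = (p$weight[husb] + p$weight[wife]) / 2
  )
  # a symmetric pair appears once per direction: keep one row per wife
  couples <- dplyr::distinct(
    couples, .data$household_id, .data$wife_pn, .keep_all = TRUE)
  list(couples = couples, skipped = skipped)
}

# Per-household composition summary used by the head-relative predicates.
household_facts <- function(p, adult_age = 18) {
  kc <- kin_class(p$relate)
  adult_male <- p$sex == "male" & !is.na(p$age) & p$age >= adult_age
  qualifying_blood <- p$relate %in%
    c("parent", "grandparent", "sibling", "nephew_niece", "cousin",
      "aunt_uncle", "grandchild", "other_relative")
  tibble::tibble(household_id = p$household_id, kc = kc,
                 adult_male = adult_male, qual = qualifying_blood,
                 relate = p$relate, sex = p$sex) |>
    dplyr::group_by(.data$household_id) |>
    dplyr::summarise(
      n_members = dplyr::n(),
      n_lateral = sum(.data$kc == "lateral_kin"),
      n_nonkin = sum(.data$kc == "non_kin"),
      n_unknown_kin = sum(.data$kc == "unknown"),
      head_sex = .data$sex[.data$relate == "head"][1],
      has_spouse_of_head = any(.data$relate == "spouse"),
      # adult male blood kin of the head besides his spouse/own children,
      # or the head's mother: the "husband's kin" set for a spouse-of-head
      # wife (case a)
      husb_kin_head = any((.data$adult_male & .data$qual)) |
        any(.data$relate == "parent" & .data$sex == "female"),
      # in-laws of the head: the husband's side when the WIFE heads (case c)
      husb_kin_wife_head = any(.data$relate == "parent_in_law") |
        any(.data$relate == "sibling_in_law" & .data$adult_male),
      .groups = "drop"
    )
}

#' Does a young wife co-reside with her husband's kin?
#'
#' Implements the patrilocality predicate for ever-married women: does the
#' household contain, beyond the couple and their own children, an adult
#' male blood relative of the husband, or the husband's mother? Resolved by
#' case analysis on the wife's relationship to the head: (a) wife is the
#' head's spouse — any of the head's father, adult male lateral or direct
#' blood kin (own children excluded), or the head's mother qualifies;
#' (b) wife is the head's child-in-law — the head is then the husband's
#' parent, so the configuration always qualifies; (c) wife heads the
#' household and the husband is her spouse — a parent-in-law or adult male
#' sibling-in-law of the head qualifies; (d) anything else is
#' indeterminate and excluded from the indicator's numerator and
#' denominator.
#'
#' @param table Validated microdata tibble.
#' @param adult_age Minimum age counting as "adult male kin" (default 18).
#' @return Tibble of ever-married women with columns `household_id`,
#'   `person_number`, and `husbands_kin` in `{"yes", "no",
#'   "indeterminate"}`.
#' @export
has_husbands_kin <- function(table, adult_age = 18) {
  p <- tibble::as_tibble(table)
  facts <- household_facts(p, adult_age = adult_age)
  ever <- c("married_in_union", "separated_divorced", "widowed")
  wives <- p |>
    dplyr::filter(.data$sex == "female", .data$marital_status %in% ever) |>
    dplyr::left_join(facts, by = "household_id")
  verdict <- dplyr::case_when(
    wives$relate == "spouse" ~ ifelse(wives$husb_kin_head, "yes", "no"),
    wives$relate == "child_in_law" ~ "yes",
    wives$relate == "head" & wives$has_spouse_of_head ~
      ifelse(wives$husb_kin_wife_head, "yes", "no"),
    .default = "indeterminate"
  )
  tibble::tibble(household_id = wives$household_id,
                 person_number = wives$person_number,
                 husbands_kin = verdict)
}

#' Is at least one lateral kin present in each person's household?
#'
#' Lateral kin (siblings, siblings-in-law, nephews/nieces, cousins,
#' aunts/uncles and, by default, other relatives) are evaluated relative to
#' the household head for every member — an approximation for non-head
#' members, which is all the relationship-to-head coding supports.
#'
#' @param table Microdata tibble.
#' @return Logical vector aligned with the rows of `table`.
#' @export
has_lateral_kin <- function(table) {
  p <- tibble::as_tibble(table)
  lat <- tapply(kin_class(p$relate) == "lateral_kin", p$household_id, any)
  unname(lat[p$household_id])
}

#' Does a person live without relatives or a spouse?
#'
#' TRUE when every other household member (possibly none) is unrelated to
#' the person: either the person is the head or the head's spouse and all
#' other members are non-kin, or the person is themselves non-kin to the
#' head and holds no spouse/mother/father pointer to (and is pointed at by)
#' nobody in the household.
#'
#' @param table Microdata tibble.
#' @return Logical vector aligned with the rows of `table`.
#' @export
lives_without_relatives <- function(table) {
  p <- tibble::as_tibble(table)
  kc <- kin_class(p$relate)
  counts <- tibble::tibble(household_id = p$household_id, kc = kc) |>
    dplyr::group_by(.data$household_id) |>
    dplyr::summarise(n = dplyr::n(), n_nonkin = sum(.data$kc == "non_kin"),
                     has_spouse = any(.data$kc == "spouse_of_head"),
                     .groups = "drop")
  i <- match(p$household_id, counts$household_id)
  n_others <- counts$n[i] - 1L
  others_nonkin <- counts$n_nonkin[i] - (kc == "non_kin")

  # pointers involving the person (held or received)
  key <- paste(p$household_id, p$person_number)
  pointed_at <- key %in% c(paste(p$household_id, p$spouse_loc),
                           paste(p$household_id, p$mother_loc),
                           paste(p$household_id, p$father_loc))
  holds_ptr <- !is.na(p$spouse_loc) | !is.na(p$mother_loc) |
    !is.na(p$father_loc)

  head_side <- kc %in% c("head", "spouse_of_head") &
    others_nonkin == n_others &
    !(kc == "head" & counts$has_spouse[i])
  nonkin_side <- kc == "non_kin" & !holds_ptr & !pointed_at
  head_side | nonkin_side
}
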