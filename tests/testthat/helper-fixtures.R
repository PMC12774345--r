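# Small programmatic fixtures: hand-built households and scenario shortcuts.

p_ <- function(hh, pn, relate, sex = "male", age = 30,
               marital = "married_in_union", region = "R1", country = "C1",
               weight = 1, spouse = NA, mother = NA, father = NA,
               urban = "urban", lf = "unknown") {
  tibble::tibble(household_id = hh, person_number = as.integer(pn),
                 region = region, country = country, weight = weight,
                 age = as.integer(age), sex = sex, marital_status = marital,
                 relate = relate, spouse_loc = as.integer(spouse),
                 mother_loc = as.integer(mother),
                 father_loc = as.integer(father), urban = urban,
                 in_labor_force = lf)
}

tab_ <- function(...) as_microdata(dplyr::bind_rows(...))

# a well-formed three-person nuclear household
nuclear_fixture <- function(hh = "H1", region = "R1", country = "C1") {
  tab_(
    p_(hh, 1, "head", "male", 30, spouse = 2, region = region, country = country),
    p_(hh, 2, "spouse", "female", 25, spouse = 1, region = region, country = country),
    p_(hh, 3, "child", "female", 4, marital = "never_married",
       mother = 2, father = 1, region = region, country = country))
}

with_seed_local <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  expr
}

# write a microdata tibble to a temporary CSV with arbitrary column names
write_raw_csv <- function(df, path) {
  readr::write_csv(df, path, progress = FALSE)
  path
}
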