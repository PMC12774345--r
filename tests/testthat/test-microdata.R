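test_that("reading a minimal well-formed person file harmonizes codes", {
  raw <- tibble::tibble(
    SERIAL = "H1", PERNUM = 1:3, GEO = "R1", CNTRY = "C1",
    AGE = c(30, 25, 4), SEX = c(1, 2, 2), MARST = c(2, 2, 1),
    RELATED = c(1000, 2000, 3000), SPLOC = c(2, 1, NA))
  path <- write_raw_csv(raw, tempfile(fileext = ".csv"))
  got <- read_microdata(path, varmap = list(
    household_id = "SERIAL", person_number = "PERNUM", region = "GEO",
    country = "CNTRY", age = "AGE", sex = "SEX", marital_status = "MARST",
    relate = "RELATED", spouse_loc = "SPLOC"))
  expect_equal(nrow(got$table), 3)
  expect_equal(got$table$relate, c("head", "spouse", "child"))
  expect_equal(got$table$sex, c("male", "female", "female"))
  expect_equal(got$table$weight, rep(1, 3))  # absent weight -> self-weighting
  expect_equal(dplyr::n_distinct(got$table$household_id), 1)
})

test_that("missing mandatory varmap role and duplicate keys are fatal", {
  raw <- tibble::tibble(SERIAL = c("H1", "H1"), PERNUM = c(1, 1),
                        GEO = "R1", CNTRY = "C1", AGE = 30, SEX = 1,
                        MARST = 2, RELATED = 1000)
  path <- write_raw_csv(raw, tempfile(fileext = ".csv"))
  expect_error(
    read_microdata(path, varmap = list(
      household_id = "SERIAL", person_number = "PERNUM", region = "GEO",
      country = "CNTRY", sex = "SEX", marital_status = "MARST",
      relate = "RELATED")),
    "age")
  expect_error(
    read_microdata(path, varmap = list(
      household_id = "SERIAL", person_number = "PERNUM", region = "GEO",
      country = "CNTRY", age = "AGE", sex = "SEX", marital_status = "MARST",
      relate = "RELATED")),
    "duplicate.*H1, 1")
})

test_that("unmappable codes harmonize to unknown and are counted", {
  raw <- tibble::tibble(SERIAL = "H1", PERNUM = 1:2, GEO = "R1",
                        CNTRY = "C1", AGE = c(30, 25), SEX = c(1, 7),
                        MARST = c(2, 2), RELATED = c(1000, 2000))
  path <- write_raw_csv(raw, tempfile(fileext = ".csv"))
  got <- read_microdata(path, varmap = list(
    household_id = "SERIAL", person_number = "PERNUM", region = "GEO",
    country = "CNTRY", age = "AGE", sex = "SEX", marital_status = "MARST",
    relate = "RELATED"))
  expect_equal(got$table$sex[2], "unknown")
  expect_equal(got$report$unmapped_codes$sex, 1)
})

test_that("write/read round-trip preserves every field", {
  tab <- nuclear_fixture()
  path <- tempfile(fileext = ".csv")
  write_microdata(tab, path)
  back <- read_microdata(path, varmap = identity_varmap())$table
  expect_equal(tibble::as_tibble(back), tibble::as_tibble(tab),
               ignore_attr = TRUE)
})

test_that("households without exactly one head are resolved per policy", {
  two_heads <- dplyr::bind_rows(
    p_("H1", 1, "head", "male", 40),
    p_("H1", 2, "head", "female", 38),
    p_("H2", 1, "head", "male", 50, spouse = 2),
    p_("H2", 2, "spouse", "female", 45, spouse = 1))
  tab <- as_microdata(two_heads)
  v <- validate_households(tab)
  expect_equal(v$report$dropped, 1)
  expect_setequal(unique(v$table$household_id), "H2")

  v2 <- validate_households(tab, policy = "oldest_male")
  expect_equal(v2$report$dropped, 0)
  h1 <- tibble::as_tibble(v2$table) |> dplyr::filter(household_id == "H1")
  expect_equal(sum(h1$relate == "head"), 1)
  expect_equal(h1$sex[h1$relate == "head"], "male")
})

test_that("asymmetric spouse pointers are symmetrized when unambiguous", {
  tab <- tab_(
    p_("H1", 1, "head", "male", 40, spouse = 2),
    p_("H1", 2, "spouse", "female", 35))   # B -> null, unique candidate
  v <- validate_households(tab)
  expect_equal(v$report$repaired_spouse, 1)
  expect_equal(tibble::as_tibble(v$table)$spouse_loc, c(2L, 1L))
})

test_that("validation is idempotent and leaves clean tables unchanged", {
  tab <- nuclear_fixture()
  v1 <- validate_households(tab)
  expect_equal(unlist(v1$report), c(dropped = 0, reheaded = 0,
                                    repaired_spouse = 0, nulled_spouse = 0,
                                    polygamous_kept = 0))
  expect_equal(tibble::as_tibble(v1$table), tibble::as_tibble(tab))

  messy <- as_microdata(dplyr::bind_rows(
    p_("H1", 1, "head", "male", 40, spouse = 2),
    p_("H1", 2, "spouse", "female", 35),
    p_("H2", 1, "head", "male", 30),
    p_("H2", 2, "head", "male", 60)))
  v1 <- validate_households(messy)
  v2 <- validate_households(v1$table)
  expect_equal(tibble::as_tibble(v2$table), tibble::as_tibble(v1$table))
  expect_equal(v2$report$repaired_spouse + v2$report$dropped, 0)
})

test_that("region covariates respect the pct_urban range contract", {
  path <- tempfile(fileext = ".csv")
  readr::write_csv(tibble::tibble(region = "R1", gni_log = 1.2,
                                  pct_urban = 1.4), path, progress = FALSE)
  expect_error(read_covariates(path), "pct_urban")
})
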