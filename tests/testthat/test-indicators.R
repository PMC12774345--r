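test_that("standard structure is the mean of country distributions", {
  # one country: its own distribution
  tab <- nuclear_fixture()
  std <- compute_standard_structure(tab)
  expect_equal(sum(std$share), 1)
  expect_equal(nrow(std), 3)  # bins 30/m, 25/f, 0/f

  # two countries with known distributions p, q -> (p+q)/2, cell by cell
  c1 <- dplyr::bind_rows(
    p_("H1", 1, "head", "male", 22, region = "R1", country = "C1"),
    p_("H1", 2, "spouse", "female", 22, region = "R1", country = "C1"))
  c2 <- dplyr::bind_rows(
    p_("H2", 1, "head", "male", 22, region = "R2", country = "C2"),
    p_("H2", 2, "lodger", "male", 47, region = "R2", country = "C2",
       marital = "never_married"))
  std2 <- compute_standard_structure(as_microdata(dplyr::bind_rows(c1, c2)))
  # oracle by direct summation: C1 = {m20:.5, f20:.5}; C2 = {m20:.5, m45:.5}
  get <- function(b, s) {
    r <- std2$share[std2$age_bin == b & std2$sex == s]
    if (length(r) == 0) 0 else r
  }
  expect_equal(get(20, "male"), 0.5)
  expect_equal(get(20, "female"), 0.25)
  expect_equal(get(45, "male"), 0.25)

  expect_error(compute_standard_structure(nuclear_fixture()[0, ]), "no persons")
})

test_that("raw indicators match direct counts on hand fixtures", {
  # id 1: 10 heads aged 20+, 2 female -> 0.2
  heads <- lapply(1:10, function(i)
    p_(paste0("H", i), 1, "head", if (i <= 2) "female" else "male", 40,
       marital = "widowed"))
  tab <- as_microdata(dplyr::bind_rows(heads))
  expect_equal(compute_raw_indicator(tab, "R1", 1)$raw, 0.2)

  # id 11: 105 boys, 100 girls aged 0-4 -> 105 (the neutral configuration)
  kids <- dplyr::bind_rows(
    p_("H1", 1, "head", "male", 40, marital = "widowed"),
    dplyr::bind_rows(lapply(1:205, function(i)
      p_("H1", 1 + i, "child", if (i <= 105) "male" else "female", 2,
         marital = "never_married"))))
  tab2 <- as_microdata(kids)
  expect_equal(compute_raw_indicator(tab2, "R1", 11)$raw, 105)

  # id 3: 4 couples, wife older in 1, equal ages in 1 -> 0.25 (tie not older)
  cpl <- function(h, ha, wa) dplyr::bind_rows(
    p_(h, 1, "head", "male", ha, spouse = 2),
    p_(h, 2, "spouse", "female", wa, spouse = 1))
  tab3 <- as_microdata(dplyr::bind_rows(
    cpl("H1", 30, 35), cpl("H2", 30, 30), cpl("H3", 40, 30),
    cpl("H4", 50, 45)))
  expect_equal(compute_raw_indicator(tab3, "R1", 3)$raw, 0.25)
})

test_that("age-standardization is the standard-weighted mean of cell rates", {
  # two female cells in the 15-19 band cannot be built from 5-year bins,
  # so use id 9 over the 15-30 band: cells 20-24 and 25-29 with rates
  # 0.1 and 0.5 and standard weights 0.25 / 0.75 -> 0.4
  mk <- function(h, age, yes) {
    kin <- if (yes) list(p_(h, 3, "parent", "female", 70,
                            marital = "widowed")) else list()
    dplyr::bind_rows(c(list(
      p_(h, 1, "head", "male", age + 2, spouse = 2),
      p_(h, 2, "spouse", "female", age, spouse = 1)), kin))
  }
  # cell 20-24: 10 wives, 1 with husband's kin; cell 25-29: 10 wives, 5 with
  rows <- c(lapply(1:10, function(i) mk(paste0("A", i), 22, i <= 1)),
            lapply(1:10, function(i) mk(paste0("B", i), 27, i <= 5)))
  tab <- as_microdata(dplyr::bind_rows(rows))
  std <- tibble::tibble(age_bin = c(20L, 25L), sex = "female",
                        share = c(0.25, 0.75))
  got <- compute_raw_indicator(tab, "R1", 9, std = std)
  expect_equal(got$value, 0.25 * 0.1 + 0.75 * 0.5)
  expect_equal(got$raw, 0.3)

  # degenerate standard concentrated on one cell equals that cell's rate
  std1 <- tibble::tibble(age_bin = 20L, sex = "female", share = 1)
  expect_equal(compute_raw_indicator(tab, "R1", 9, std = std1)$value, 0.1)

  # cells absent from the region are dropped and weights renormalized
  std3 <- tibble::tibble(age_bin = c(15L, 20L, 25L), sex = "female",
                         share = c(0.5, 0.125, 0.375))
  expect_equal(compute_raw_indicator(tab, "R1", 9, std = std3)$value, 0.4)
})

test_that("the matrix equals cell-wise indicator calls and flags missing", {
  gen <- generate_dataset(list(
    scenario_config(region = "R1", n_households = 60, seed = 5),
    scenario_config(region = "R2", country = "C2", n_households = 60,
                    seed = 5)))$table
  std <- compute_standard_structure(gen)
  mat <- compute_indicator_matrix(gen, std = std)
  expect_equal(nrow(mat), 22)
  for (id in c(1, 4, 7, 11)) {
    for (r in c("R1", "R2")) {
      one <- compute_raw_indicator(gen, r, id, std = std)
      row <- mat[mat$region == r & mat$id == id, ]
      expect_equal(row$raw, one$raw)
      expect_equal(row$value, one$value)
    }
  }

  # a region with no men aged 65+ leaves id 5 missing
  nuc <- nuclear_fixture(region = "R9")
  mat2 <- compute_indicator_matrix(nuc)
  expect_true(mat2$missing[mat2$id == 5])
  expect_true(mat2$missing[mat2$id == 7])
})

test_that("weighted proportions are invariant to rescaling all weights", {
  gen <- tibble::as_tibble(generate_region(
    scenario_config(n_households = 80, seed = 21)))
  mat1 <- compute_indicator_matrix(as_microdata(gen))
  gen$weight <- gen$weight * 3.7
  mat2 <- compute_indicator_matrix(as_microdata(gen))
  expect_equal(mat1$raw, mat2$raw)
  expect_equal(mat1$value, mat2$value)
  ok <- !mat1$missing & mat1$id <= 10
  expect_true(all(mat1$raw[ok] >= 0 & mat1$raw[ok] <= 1))
  expect_true(all(mat1$raw[mat1$id == 11 & !mat1$missing] >= 0))
})

test_that("raw indicators recover their generating parameters", {
  # moderate-size scenarios per parameter; the full large-sample recovery
  # of all eleven indicators lives in the acceptance suite
  tol3se <- function(p, n) 3 * sqrt(p * (1 - p) / n)

  # indicator 2 via p_teen_married on an all-nuclear region without teen wives
  cfg <- scenario_config(region = "T2", n_households = 1500, seed = 31,
                         archetype_mix = c(nuclear_couple = 1),
                         p_teen_married = 0.3,
                         husband_age_range = c(35, 50),
                         age_gap_range = c(0, 4))
  tab <- generate_region(cfg)
  got <- compute_raw_indicator(tab, "T2", 2)
  expect_lt(abs(got$raw - 0.3), tol3se(0.3, got$denom))

  # indicator 3 via p_wife_older
  cfg3 <- scenario_config(region = "T3", n_households = 2000, seed = 32,
                          archetype_mix = c(nuclear_couple = 1),
                          p_wife_older = 0.2)
  got3 <- compute_raw_indicator(generate_region(cfg3), "T3", 3)
  expect_lt(abs(got3$raw - 0.2), tol3se(0.2, got3$denom))

  # indicator 8 via p_elder_alone on elder-centred households
  cfg8 <- scenario_config(region = "T8", n_households = 2000, seed = 33,
                          archetype_mix = c(solitary_elder = 1),
                          p_teen_married = 0, p_elder_alone = 0.4)
  got8 <- compute_raw_indicator(generate_region(cfg8), "T8", 8)
  expect_lt(abs(got8$raw - 0.4), tol3se(0.4, got8$denom))
})
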