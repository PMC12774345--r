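test_that("intensity adjustment makes every indicator point the same way", {
  expect_equal(patriarchal_intensity(0.3, 2), 0.3)    # + passes through
  expect_equal(patriarchal_intensity(0.2, 1), 0.8)    # - complemented
  expect_equal(patriarchal_intensity(112, 11), 112)   # ratio passes through
  expect_true(is.na(patriarchal_intensity(NA_real_, 1)))
})

test_that("scaling maps the floor to 0 and the benchmark region to 10", {
  expect_equal(scale_indicator(c(0, 0.2, 0.4), 2), c(0, 5, 10))
  # clamping below the neutral under-five sex ratio
  expect_equal(scale_indicator(c(103, 110, 120), 11), c(0, 10 * 5 / 15, 10))
  # no variation above the floor: all zero
  expect_equal(scale_indicator(c(0.51, 0.51), 10), c(0, 0))
  # fixed benchmark below the minimum is rejected
  expect_error(scale_indicator(c(0.6), 10, benchmark = 0.4), "benchmark")
  # missing propagates
  expect_equal(scale_indicator(c(0.1, NA, 0.2), 2), c(5, NA, 10))
})

test_that("nested aggregation follows the domain means and their sum", {
  regs <- "R1"
  sc <- tibble::tibble(region = regs, id = 1:11,
                       score = c(rep(8, 4), rep(6, 4), 10, 2, 2))
  got <- assemble_pi(sc)
  expect_equal(got$male_domination, 8)
  expect_equal(got$generational_domination, 6)
  expect_equal(got$patrilocality, 10)
  expect_equal(got$son_preference, 2)
  expect_equal(got$pi, 26)

  # extremes of the range
  expect_equal(assemble_pi(tibble::tibble(region = "R", id = 1:11,
                                          score = rep(10, 11)))$pi, 40)
  expect_equal(assemble_pi(tibble::tibble(region = "R", id = 1:11,
                                          score = rep(0, 11)))$pi, 0)

  # a missing member is excluded from its domain mean; an all-missing
  # domain makes the region's index missing
  sc$score[9] <- NA
  got2 <- assemble_pi(sc)
  expect_true(is.na(got2$pi))
  expect_equal(got2$n_missing, 1)
  sc$score[9] <- 4; sc$score[10] <- NA
  got3 <- assemble_pi(sc)
  expect_equal(got3$son_preference, 2)
  expect_equal(got3$pi, 8 + 6 + 4 + 2)
})

test_that("index is monotone in any single region's intensity", {
  base <- list(A = c(0.2, 0.5, 0.3), B = c(0.4, 0.1, 0.6))
  spec2 <- indicator_registry()[2, ]
  pi_of <- function(ints) {
    sc <- scale_indicator(ints, spec2)
    sc
  }
  s0 <- pi_of(c(0.2, 0.4, 0.3))
  s1 <- pi_of(c(0.35, 0.4, 0.3))  # raise region 1 only
  expect_gte(s1[1], s0[1])
  expect_lte(s1[2], s0[2])        # others can only fall (benchmark rises)
  expect_lte(s1[3], s0[3])

  # full-pipeline check on generated data: raising teen marriage in one
  # region does not lower its index, holding companions fixed
  mk <- function(p) generate_dataset(list(
    scenario_config(region = "X", n_households = 150, seed = 9,
                    p_teen_married = p),
    scenario_config(region = "Y", country = "C2", n_households = 150,
                    seed = 9)))$table
  lo <- compute_pi(mk(0.05), standardize = FALSE)
  hi <- compute_pi(mk(0.9), standardize = FALSE)
  pi_x <- function(r) r$pi$pi[r$pi$region == "X"]
  expect_gt(pi_x(hi), pi_x(lo))
})

test_that("scores are permutation-equivariant and duplicate-region stable", {
  ints <- c(R1 = 0.1, R2 = 0.3, R3 = 0.25)
  s <- scale_indicator(ints, 2)
  perm <- c(3, 1, 2)
  expect_equal(scale_indicator(ints[perm], 2), s[perm])
  # adding a duplicate of an existing region changes no score
  s_dup <- scale_indicator(c(ints, R2b = 0.3), 2)
  expect_equal(unname(s_dup[1:3]), unname(s))
})

test_that("all scores stay in range on generated data", {
  gen <- generate_dataset(list(
    scenario_config(region = "R1", n_households = 80, seed = 41),
    scenario_config(region = "R2", country = "C2", n_households = 80,
                    seed = 41, p_teen_married = 0.5),
    scenario_config(region = "R3", country = "C3", n_households = 80,
                    seed = 41, p_wife_older = 0.4)))$table
  res <- compute_pi(gen)
  sc <- res$scores$score[!is.na(res$scores$score)]
  expect_true(all(sc >= 0 & sc <= 10))
  expect_true(all(res$pi$pi >= 0 & res$pi$pi <= 40, na.rm = TRUE))
  # domain scores equal the member means
  r1 <- res$scores[res$scores$region == "R1", ]
  expect_equal(res$pi$male_domination[res$pi$region == "R1"],
               mean(r1$score[r1$id %in% 1:4], na.rm = TRUE))
  expect_equal(res$pi$pi[res$pi$region == "R1"],
               sum(res$pi[res$pi$region == "R1",
                          c("male_domination", "generational_domination",
                            "patrilocality", "son_preference")]))
})

test_that("country-level benchmarking reuses the same pipeline over countries", {
  gen <- generate_dataset(list(
    scenario_config(region = "R1", country = "C1", n_households = 60,
                    seed = 51),
    scenario_config(region = "R2", country = "C1", n_households = 60,
                    seed = 51),
    scenario_config(region = "R3", country = "C2", n_households = 60,
                    seed = 51, p_teen_married = 0.6)))$table
  res <- compute_pi(gen, level = "country")
  expect_setequal(res$pi$region, c("C1", "C2"))
  expect_true(all(res$pi$pi >= 0 & res$pi$pi <= 40, na.rm = TRUE))
})
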