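test_that("couples form from pointers, relate fallback, and polygamy", {
  # symmetric pointers
  tab <- nuclear_fixture()
  got <- identify_couples(tab)
  expect_equal(nrow(got$couples), 1)
  expect_equal(got$couples$husband_age, 30L)
  expect_equal(got$couples$wife_age, 25L)

  # female head, relate fallback (no pointers), plus unmarried adult child
  tab2 <- tab_(
    p_("H1", 1, "head", "female", 40),
    p_("H1", 2, "spouse", "male", 35),
    p_("H1", 3, "child", "male", 20, marital = "never_married"))
  got2 <- identify_couples(tab2)
  expect_equal(nrow(got2$couples), 1)
  expect_true(got2$couples$wife_age > got2$couples$husband_age)

  # siblings only: no spousal links
  tab3 <- tab_(
    p_("H1", 1, "head", "male", 50, marital = "never_married"),
    p_("H1", 2, "sibling", "male", 45, marital = "never_married"))
  expect_equal(nrow(identify_couples(tab3)$couples), 0)

  # polygamy: two wives pointing at one husband -> one couple per wife
  tab4 <- as_microdata(dplyr::bind_rows(
    p_("H1", 1, "head", "male", 50),
    p_("H1", 2, "spouse", "female", 40, spouse = 1),
    p_("H1", 3, "spouse", "female", 30, spouse = 1)))
  got4 <- identify_couples(validate_households(tab4)$table)
  expect_equal(nrow(got4$couples), 2)
  expect_equal(sort(got4$couples$wife_age), c(30L, 40L))
})

test_that("no person appears twice in the same couple role", {
  gen <- generate_region(scenario_config(n_households = 120, seed = 11))
  cps <- identify_couples(gen)$couples
  expect_equal(anyDuplicated(paste(cps$household_id, cps$wife_pn)), 0)
})

test_that("husbands-kin case analysis follows the household configuration", {
  # (b) daughter-in-law with a male head aged 60 -> yes
  tab <- tab_(
    p_("H1", 1, "head", "male", 60),
    p_("H1", 2, "child", "male", 30, spouse = 3),
    p_("H1", 3, "child_in_law", "female", 25, spouse = 2))
  hk <- has_husbands_kin(tab)
  expect_equal(hk$husbands_kin[hk$person_number == 3], "yes")

  # (a) wife of head in a pure nuclear household -> no
  hk2 <- has_husbands_kin(nuclear_fixture())
  expect_equal(hk2$husbands_kin[hk2$person_number == 2], "no")

  # (a) wife of head with the head's mother present -> yes
  tab3 <- tab_(
    p_("H1", 1, "head", "male", 40, spouse = 2),
    p_("H1", 2, "spouse", "female", 35, spouse = 1),
    p_("H1", 3, "parent", "female", 70, marital = "widowed"))
  hk3 <- has_husbands_kin(tab3)
  expect_equal(hk3$husbands_kin[hk3$person_number == 2], "yes")

  # (c) female head whose husband is spouse-of-head, his brother present
  tab4 <- tab_(
    p_("H1", 1, "head", "female", 35, spouse = 2),
    p_("H1", 2, "spouse", "male", 38, spouse = 1),
    p_("H1", 3, "sibling_in_law", "male", 30, marital = "never_married"))
  hk4 <- has_husbands_kin(tab4)
  expect_equal(hk4$husbands_kin[hk4$person_number == 1], "yes")

  # (d) "other relative" wife with no resolvable husband -> indeterminate
  tab5 <- tab_(
    p_("H1", 1, "head", "male", 60),
    p_("H1", 2, "other_relative", "female", 25))
  hk5 <- has_husbands_kin(tab5)
  expect_equal(hk5$husbands_kin[hk5$person_number == 2], "indeterminate")
})

test_that("husbands-kin is never yes for a couple living only with own children", {
  # property over several relate codings of the couple
  for (head_is_wife in c(FALSE, TRUE)) {
    hsex <- if (head_is_wife) "female" else "male"
    tab <- tab_(
      p_("H1", 1, "head", hsex, 35, spouse = 2),
      p_("H1", 2, "spouse", if (head_is_wife) "male" else "female", 33,
         spouse = 1),
      p_("H1", 3, "child", "male", 10, marital = "never_married"),
      p_("H1", 4, "child", "female", 17, marital = "never_married"))
    hk <- has_husbands_kin(tab)
    wife_pn <- if (head_is_wife) 1 else 2
    expect_false(hk$husbands_kin[hk$person_number == wife_pn] == "yes")
  }
})

test_that("lateral-kin presence is evaluated from the head's perspective", {
  tab <- tab_(
    p_("H1", 1, "head", "male", 70, marital = "widowed"),
    p_("H1", 2, "sibling", "male", 68, marital = "widowed"))
  expect_true(all(has_lateral_kin(tab)))

  tab2 <- tab_(
    p_("H1", 1, "head", "male", 70, spouse = 2),
    p_("H1", 2, "spouse", "female", 66, spouse = 1),
    p_("H1", 3, "child", "male", 40, marital = "never_married"))
  expect_false(any(has_lateral_kin(tab2)))

  # elderly parent of the head counts as with-lateral-kin when the head's
  # sibling co-resides (head-perspective approximation)
  tab3 <- tab_(
    p_("H1", 1, "head", "male", 45),
    p_("H1", 2, "parent", "female", 75, marital = "widowed"),
    p_("H1", 3, "sibling", "male", 40, marital = "never_married"))
  lat <- has_lateral_kin(tab3)
  expect_true(lat[2])
})

test_that("living without relatives or spouse follows the head-relative rule", {
  solo <- tab_(p_("H1", 1, "head", "male", 70, marital = "widowed"))
  expect_true(lives_without_relatives(solo))

  with_grandchild <- tab_(
    p_("H1", 1, "head", "female", 70, marital = "widowed"),
    p_("H1", 2, "grandchild", "male", 12, marital = "never_married"))
  expect_false(any(lives_without_relatives(with_grandchild)))

  # elderly lodger without pointers inside a family household
  lodger <- tab_(
    p_("H1", 1, "head", "male", 40, spouse = 2),
    p_("H1", 2, "spouse", "female", 38, spouse = 1),
    p_("H1", 3, "lodger", "male", 70, marital = "widowed"))
  lw <- lives_without_relatives(lodger)
  expect_equal(lw, c(FALSE, FALSE, TRUE))

  # head living only with employees
  staff <- tab_(
    p_("H1", 1, "head", "male", 80, marital = "widowed"),
    p_("H1", 2, "employee", "female", 30, marital = "never_married"))
  expect_true(lives_without_relatives(staff)[1])
})

test_that("kinship predicates are pure functions of the household records", {
  tab <- nuclear_fixture()
  before <- tibble::as_tibble(tab)
  invisible(identify_couples(tab))
  invisible(has_husbands_kin(tab))
  invisible(has_lateral_kin(tab))
  invisible(lives_without_relatives(tab))
  expect_identical(tibble::as_tibble(tab), before)
  # repeated calls agree
  expect_identical(has_husbands_kin(tab), has_husbands_kin(tab))
})
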