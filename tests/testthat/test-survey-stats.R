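test_that("wealth score spans 0 (no assets) to 100 (all assets)", {
  hh <- tibble::tibble(
    household_id = 1:3, residence = "rural", size = c(4, 4, 4),
    asset_01 = c(1, 0, 1), asset_02 = c(1, 0, 0), asset_03 = c(1, 0, 1)
  )
  md <- structure(list(households = hh,
                       persons = tibble::tibble(household_id = rep(1:3, 4)),
                       deaths = tibble::tibble()),
                  class = "dcea_microdata")
  out <- compute_wealth_index(md)$households
  expect_equal(out$wealth_score, c(100, 0, 100 * 2 / 3))
})

test_that("index score increases with the generator's latent wealth", {
  md <- generate_households(small_synth_config(n = 5000, seed = 21))
  md <- compute_wealth_index(md)
  mean_by_latent <- tapply(md$households$wealth_score,
                           md$households$latent_quintile, mean)
  expect_true(all(diff(mean_by_latent) > 0))
  # quintiles partition persons into five near-equal blocks
  persons_per_q <- tapply(md$households$size, md$households$wealth_quintile, sum)
  expect_true(max(abs(persons_per_q / sum(persons_per_q) - 0.2)) < 0.02)
})

test_that("prevalence shares, uptake and oc shares match their definitions", {
  md <- make_quintile_microdata(cases = c(36, 16, 23, 13, 12),
                                seekers = c(17, 6, 11, 6, 5))
  d <- estimate_prevalence_shares(md, "rotavirus")
  expect_equal(unname(d), c(0.36, 0.16, 0.23, 0.13, 0.12))
  expect_equal(sum(d), 1)

  e <- estimate_uptake(md, "rotavirus")
  expect_equal(unname(e), c(17, 6, 11, 6, 5) / c(36, 16, 23, 13, 12))

  f <- estimate_opportunity_cost_shares(md)
  expect_equal(unname(f), c(17, 6, 11, 6, 5) / 45)

  # all episodes in rural households -> residence shares (1, 0)
  f_res <- estimate_opportunity_cost_shares(
    make_quintile_microdata(cases = c(10, 10, 10, 0, 0),
                            seekers = c(5, 5, 5, 0, 0)),
    dimension = "residence")
  expect_equal(unname(f_res), c(1, 0))
})

test_that("degenerate survey patterns are handled explicitly", {
  md <- make_quintile_microdata(cases = c(10, 0, 0, 0, 0), seekers = c(10, 0, 0, 0, 0))
  expect_equal(unname(estimate_prevalence_shares(md, "rotavirus")),
               c(1, 0, 0, 0, 0))
  e <- estimate_uptake(md, "rotavirus")
  expect_equal(unname(e[1]), 1)
  expect_true(all(is.na(e[2:5])))

  expect_warning(d <- estimate_prevalence_shares(md, "not_a_disease"),
                 "no reported cases")
  expect_true(all(is.na(d)))

  none <- make_quintile_microdata(seekers = c(0, 0, 0, 0, 0))
  expect_error(estimate_opportunity_cost_shares(none), "no public")

  # non-public providers excluded from numerator and denominator
  other <- make_quintile_microdata(provider = "other")
  expect_error(estimate_opportunity_cost_shares(other), "no public")
})

test_that("estimators are invariant to person row order", {
  md <- make_quintile_microdata(seekers = c(17, 6, 11, 6, 5))
  set.seed(1)
  shuffled <- md
  shuffled$persons <- md$persons[sample(nrow(md$persons)), ]
  expect_equal(estimate_prevalence_shares(md, "rotavirus"),
               estimate_prevalence_shares(shuffled, "rotavirus"))
  expect_equal(estimate_uptake(md, "rotavirus"),
               estimate_uptake(shuffled, "rotavirus"))
  expect_equal(estimate_opportunity_cost_shares(md),
               estimate_opportunity_cost_shares(shuffled))
})

test_that("missing prevalence vectors get the renormalized mean distribution", {
  sch <- box1_scheme()
  tbl <- rbind(
    new_share_table_for_test("a", c(0.4, 0.1, 0.2, 0.2, 0.1), sch),
    new_share_table_for_test("b", c(0.2, 0.3, 0.2, 0.2, 0.1), sch),
    new_share_table_for_test("c", rep(NA_real_, 5), sch)
  )
  done <- impute_missing_prevalence(tbl)
  imputed <- done$value[done$intervention == "c"]
  expect_equal(imputed, c(0.3, 0.2, 0.2, 0.2, 0.1))
  expect_true(all(done$imputed[done$intervention == "c"]))
  expect_false(any(done$imputed[done$intervention != "c"]))

  # one observed vector only -> copied
  tbl1 <- rbind(new_share_table_for_test("a", c(0.4, 0.1, 0.2, 0.2, 0.1), sch),
                new_share_table_for_test("c", rep(NA_real_, 5), sch))
  expect_equal(impute_missing_prevalence(tbl1)$value[6:10],
               c(0.4, 0.1, 0.2, 0.2, 0.1))

  # no missing -> identity
  full <- rbind(new_share_table_for_test("a", c(0.4, 0.1, 0.2, 0.2, 0.1), sch))
  expect_identical(impute_missing_prevalence(full)$value, full$value)

  allmiss <- new_share_table_for_test("c", rep(NA_real_, 5), sch)
  expect_error(impute_missing_prevalence(allmiss), "nothing to impute")
})

test_that("missing uptake entries get the subgroup mean across interventions", {
  sch <- box1_scheme()
  tbl <- rbind(
    new_share_table_for_test("a", c(0.4, 0.5, 0.5, 0.5, 0.5), sch, kind = "uptake_rate"),
    new_share_table_for_test("b", c(0.6, 0.5, 0.5, 0.5, 0.5), sch, kind = "uptake_rate"),
    new_share_table_for_test("c", c(NA, 0.7, NA, NA, NA), sch, kind = "uptake_rate")
  )
  done <- impute_missing_uptake(tbl)
  cvals <- done$value[done$intervention == "c"]
  expect_equal(cvals[1], 0.5)        # mean of 0.4, 0.6 in poorest
  expect_equal(cvals[2], 0.7)        # observed entry kept
  expect_equal(cvals[3], 0.5)
  flags <- done$imputed[done$intervention == "c"]
  expect_equal(flags, c(TRUE, FALSE, TRUE, TRUE, TRUE))

  expect_identical(impute_missing_uptake(tbl[1:10, ])$value, tbl$value[1:10])

  gap <- rbind(new_share_table_for_test("a", c(NA, 0.5, 0.5, 0.5, 0.5), sch,
                                        kind = "uptake_rate"))
  expect_error(impute_missing_uptake(gap), "poorest")
})

test_that("estimate_shares recovers a complete, valid input set", {
  cfg <- small_synth_config(n = 3000, seed = 14)
  md <- generate_survey(cfg)
  est <- estimate_shares(md)
  per_int <- split(est$prevalence$value, est$prevalence$intervention)
  for (v in per_int) expect_equal(sum(v), 1, tolerance = 1e-9)
  expect_true(all(est$uptake$value >= 0 & est$uptake$value <= 1))
  expect_equal(sum(est$oc_shares), 1, tolerance = 1e-12)
})
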