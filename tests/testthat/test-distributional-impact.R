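test_that("eligible populations allocate by prevalence share and conserve totals", {
  d <- c(0.36, 0.16, 0.23, 0.13, 0.12)
  e <- allocate_eligible(521300, d)
  expect_equal(e[1], 521300 * 0.36)
  expect_equal(sum(e), 521300)
  expect_equal(allocate_eligible(521300, c(1, 0, 0, 0, 0)),
               c(521300, 0, 0, 0, 0))
  expect_equal(allocate_eligible(0, d), rep(0, 5))
  expect_error(allocate_eligible(100, c(0.5, NA, 0.5, 0, 0)), "impute")
})

test_that("direct benefit is A*B*D*E with validated uptake", {
  inp <- box1_inputs()
  b <- direct_benefit_distribution(521300, 0.14, inp$prevalence, inp$uptake)
  expect_equal(round(b[[1]]), 12611)
  full <- direct_benefit_distribution(521300, 0.14, inp$prevalence, rep(1, 5))
  expect_equal(round(sum(full)), 72982)
  expect_equal(unname(direct_benefit_distribution(521300, 0, inp$prevalence,
                                                  inp$uptake)),
               rep(0, 5))
  expect_error(direct_benefit_distribution(10, 0.1, inp$prevalence,
                                           c(1.2, 0.5, 0.5, 0.5, 0.5)),
               "\\[0, 1\\]")
})

test_that("opportunity cost distributes F * cost/k and is linear in cost", {
  oc <- box1_oc()
  dist <- opportunity_cost_distribution(809318, oc)
  expect_equal(round(dist[[1]]), 3052)
  expect_equal(sum(dist), 809318 / 61)
  expect_equal(opportunity_cost_distribution(0, oc), rep(0, 5),
               ignore_attr = TRUE)
  expect_equal(opportunity_cost_distribution(2 * 809318, oc), 2 * dist)
  flat <- oc_model(1, rep(0.2, 5), box1_scheme())
  expect_equal(unname(opportunity_cost_distribution(100, flat)), rep(20, 5))
  expect_error(oc_model(0, rep(0.2, 5), box1_scheme()), "positive")
})

test_that("total cost supports the three costing conventions", {
  inp <- box1_inputs()
  expect_equal(total_cost(521300, 0.69, mode = "fixed", fixed = 809318), 809318)
  expect_equal(total_cost(521300, 0.69, mode = "per_eligible"), 359697)
  expect_equal(total_cost(521300, 0.69, inp$prevalence, inp$uptake,
                          mode = "per_treated"),
               521300 * 0.69 * sum(inp$prevalence * inp$uptake))
  expect_equal(total_cost(521300, 0, mode = "per_eligible"), 0)
  expect_equal(total_cost(521300, 0, inp$prevalence, inp$uptake,
                          mode = "per_treated"), 0)
  expect_error(total_cost(1, 1, mode = "fixed"), "fixed")
})

test_that("net benefit distribution nets benefits against opportunity cost", {
  inp <- box1_inputs()
  direct <- direct_benefit_distribution(521300, 0.14, inp$prevalence, inp$uptake)
  ocd <- opportunity_cost_distribution(809318, inp$oc)
  res <- net_benefit_distribution(direct, ocd, inp$scheme)
  expect_equal(round(sum(res$net_benefit)), 20034)
  expect_equal(round(res$net_benefit[1]), 9560)
  expect_equal(round(res$nhb_share[1], 2), 0.48)
  zero <- net_benefit_distribution(direct, direct, inp$scheme)
  expect_equal(zero$net_benefit, rep(0, 5))
  expect_true(all(is.na(zero$nhb_share)))
})

test_that("stage-1 conservation and brute-force equivalence hold on random instances", {
  sch <- box1_scheme()
  set.seed(99)
  for (i in 1:25) {
    A <- runif(1, 1e3, 1e6)
    B <- runif(1, 0.001, 2)
    C <- runif(1, 0.1, 100)
    D <- rand_shares()
    E <- runif(5)
    F <- rand_shares()
    k <- runif(1, 20, 150)
    oc <- oc_model(k, F, sch)
    rec <- tibble::tibble(name = "x", eligible_population = A,
                          incremental_cost = C, incremental_benefit = B,
                          in_ehp = TRUE)
    res <- dcea:::impact_one(rec, D, E, oc, cost_mode = "per_treated")
    tc <- A * C * sum(D * E)
    # conservation identities
    expect_equal(sum(res$eligible), A, tolerance = 1e-9)
    expect_equal(sum(res$opportunity_cost), tc / k, tolerance = 1e-9)
    expect_equal(sum(res$net_benefit), sum(res$direct_benefit) - tc / k,
                 tolerance = 1e-9)
    # element-by-element oracle
    for (g in 1:5) {
      expect_equal(res$eligible[g], A * D[g])
      expect_equal(res$treated[g], A * D[g] * E[g])
      expect_equal(res$direct_benefit[g], A * B * D[g] * E[g])
      expect_equal(res$opportunity_cost[g], F[g] * tc / k)
      expect_equal(res$net_benefit[g], A * B * D[g] * E[g] - F[g] * tc / k)
    }
    # monotonicity in uptake at fixed cost
    E2 <- pmin(E + 0.1, 1)
    d1 <- direct_benefit_distribution(A, B, D, E)
    d2 <- direct_benefit_distribution(A, B, D, E2)
    ocd <- opportunity_cost_distribution(tc, oc)
    expect_true(all(d2 - ocd >= d1 - ocd - 1e-12))
  }
})

test_that("full coverage sets uptake to one and scales cost by convention", {
  inp <- box1_inputs()
  full <- full_coverage_scenario(inp$record, inp$prevalence, inp$uptake,
                                 inp$oc, cost_mode = "fixed",
                                 fixed_cost = 809318)
  expect_equal(round(sum(full$direct_benefit)), 72982)
  expect_equal(full$treated, full$eligible)
  # fixed cost scales with service volume: x 1/sum(D*E)
  expect_equal(sum(full$opportunity_cost),
               809318 / sum(inp$prevalence * inp$uptake) / 61)

  # already at full uptake -> idempotent
  rec <- inp$record
  again <- full_coverage_scenario(rec, inp$prevalence, rep(1, 5), inp$oc,
                                  cost_mode = "per_treated")
  cur <- dcea:::impact_one(rec, inp$prevalence, rep(1, 5), inp$oc,
                           cost_mode = "per_treated")
  expect_equal(again$net_benefit, cur$net_benefit)

  # a subgroup can lose from expanded coverage when its oc growth
  # outpaces its benefit growth
  sch <- box1_scheme()
  oc_rich <- oc_model(61, c(0.05, 0.05, 0.05, 0.05, 0.8), sch)
  rec2 <- tibble::tibble(name = "y", eligible_population = 1e5,
                         incremental_cost = 5, incremental_benefit = 0.05,
                         in_ehp = TRUE)
  D <- c(0.4, 0.3, 0.2, 0.08, 0.02)
  E <- c(0.5, 0.5, 0.5, 0.5, 0.9)
  cur2 <- dcea:::impact_one(rec2, D, E, oc_rich, cost_mode = "per_treated")
  full2 <- full_coverage_scenario(rec2, D, E, oc_rich, cost_mode = "per_treated")
  expect_lt(full2$net_benefit[5], cur2$net_benefit[5])
})

test_that("catalog-level impact stacks per-intervention results", {
  gen <- generate_intervention_catalog(12, seed = 8)
  oc <- box1_oc()
  imp <- distributional_impact(gen$catalog, gen$prevalence, gen$uptake, oc)
  expect_equal(nrow(imp), 12 * 5)
  tots <- impact_totals(imp)
  expect_equal(nrow(tots), 12)
  # full-coverage benefit never below current-uptake benefit
  impf <- distributional_impact(gen$catalog, gen$prevalence, gen$uptake, oc,
                                scenario = "full_coverage")
  expect_true(all(impf$direct_benefit >= imp$direct_benefit - 1e-12))
})
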