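test_that("EDE matches closed forms for flat, two-point and limiting cases", {
  flat <- tibble::tibble(hale = rep(50, 5), weight = rep(0.2, 5))
  for (eps in c(0, 1, 2, 10, 25)) {
    r <- atkinson_ede(flat, aversion = eps)
    expect_equal(r$ede, 50)
    expect_equal(r$atkinson, 0)
  }

  two <- tibble::tibble(hale = c(40, 60), weight = c(0.5, 0.5))
  expect_equal(atkinson_ede(two, aversion = 2)$ede, 2 / (1 / 40 + 1 / 60))
  expect_equal(atkinson_ede(two, aversion = 0)$ede, 50)
  expect_equal(atkinson_ede(two, aversion = 1)$ede, sqrt(40 * 60))

  expect_error(atkinson_ede(tibble::tibble(hale = c(-1, 50),
                                           weight = c(0.5, 0.5)),
                            aversion = 2), "positive")
})

test_that("EDE <= mean with equality iff the distribution is flat", {
  set.seed(7)
  for (i in 1:100) {
    d <- tibble::tibble(hale = runif(5, 20, 80), weight = rand_shares())
    eps <- runif(1, 0.5, 25)
    r <- atkinson_ede(d, aversion = eps)
    expect_lte(r$ede, r$mean + 1e-12)
    if (max(d$hale) - min(d$hale) > 1e-6) expect_lt(r$ede, r$mean)
  }
})

test_that("EDE is continuous in the aversion parameter at one", {
  d <- tibble::tibble(hale = c(45, 50, 52, 55, 60), weight = rep(0.2, 5))
  geo <- exp(sum(0.2 * log(d$hale)))
  expect_equal(atkinson_ede(d, aversion = 1)$ede, geo, tolerance = 1e-12)
  expect_equal(atkinson_ede(d, aversion = 1 + 1e-7)$ede, geo, tolerance = 1e-9)
  expect_equal(atkinson_ede(d, aversion = 1 - 1e-7)$ede, geo, tolerance = 1e-9)
})

test_that("mean-preserving transfers to worse-off groups never reduce EDE", {
  set.seed(13)
  for (i in 1:200) {
    h <- sort(runif(5, 20, 80))  # index 1 worst off
    w <- rep(0.2, 5)
    from <- sample(2:5, 1)
    to <- sample(seq_len(from - 1), 1)
    amount <- runif(1, 0, (h[from] - h[to]) / 2)
    h2 <- h; h2[from] <- h[from] - amount; h2[to] <- h[to] + amount
    eps <- runif(1, 0.5, 15)
    e1 <- atkinson_ede(tibble::tibble(hale = h, weight = w), aversion = eps)$ede
    e2 <- atkinson_ede(tibble::tibble(hale = h2, weight = w), aversion = eps)$ede
    expect_gte(e2, e1 - 1e-10)
  }
})

test_that("tidy and glance expose the EDE decomposition", {
  d <- tibble::tibble(hale = c(49.15, 53.18), weight = c(0.15, 0.85))
  r <- atkinson_ede(d, aversion = 10)
  td <- tidy(r)
  expect_equal(td$estimate[td$term == "cost_of_inequality"],
               r$mean - r$ede)
  gl <- glance(r)
  expect_equal(gl$aversion, 10)
  expect_equal(gl$n_groups, 2)
})

test_that("interventions shift baseline HALE by per-person net benefit", {
  base <- structure(
    tibble::tibble(subgroup = factor(quintile_labels, levels = quintile_labels),
                   hale = c(50, 51, 52, 53, 54),
                   population = rep(1e6, 5), weight = rep(0.2, 5)),
    class = c("dcea_hale", class(tibble::tibble())))

  same <- apply_intervention(base, rep(0, 5))
  expect_equal(same$hale, base$hale)

  poor_only <- apply_intervention(base, c(0.85e6, 0, 0, 0, 0))
  expect_equal(poor_only$hale, base$hale + c(0.85, 0, 0, 0, 0))

  # uniform per-person gain c: mean rises by exactly c; the EDE rises by at
  # least c (the EDE is concave and homogeneous, hence superadditive, and
  # relative inequality falls under translation) and by at most c plus the
  # baseline cost of inequality
  unif <- apply_intervention(base, rep(2e6, 5))
  for (eps in c(2, 10)) {
    e0 <- atkinson_ede(base, aversion = eps)
    e1 <- atkinson_ede(unif, aversion = eps)
    expect_equal(e1$mean - e0$mean, 2)
    expect_gte(e1$ede - e0$ede, 2 - 1e-12)
    expect_lte(e1$ede - e0$ede, 2 + e0$cost_of_inequality + 1e-12)
  }

  expect_error(apply_intervention(base, rep(-60e6, 5)), "non-positive")
})

test_that("equity impact signs follow who receives the benefit", {
  base <- structure(
    tibble::tibble(subgroup = factor(quintile_labels, levels = quintile_labels),
                   hale = c(48, 50, 52, 54, 56),
                   population = rep(1e6, 5), weight = rep(0.2, 5)),
    class = c("dcea_hale", class(tibble::tibble())))

  origin <- equity_impact(base, base, aversion = 10)
  expect_equal(origin$dnhb, 0)
  expect_equal(origin$dede, 0)

  to_poor <- equity_impact(base, apply_intervention(base, c(1e6, 0, 0, 0, 0)),
                           aversion = 10)
  expect_gt(to_poor$inequality_impact, 0)
  expect_equal(to_poor$dnhb, 1e6, tolerance = 1e-6)

  to_rich <- equity_impact(base, apply_intervention(base, c(0, 0, 0, 0, 1e6)),
                           aversion = 10)
  expect_lt(to_rich$inequality_impact, 0)
  expect_equal(to_rich$quadrant, "Q2 (+,-)")
})

test_that("rankings, selected sets and quadrant counts are consistent", {
  base <- structure(
    tibble::tibble(subgroup = factor(quintile_labels, levels = quintile_labels),
                   hale = c(48, 50, 52, 54, 56),
                   population = rep(1e6, 5), weight = rep(0.2, 5)),
    class = c("dcea_hale", class(tibble::tibble())))
  gen <- generate_intervention_catalog(30, seed = 5)
  imp <- distributional_impact(gen$catalog, gen$prevalence, gen$uptake, box1_oc())
  plane <- equity_plane(imp, base, aversion = 10, catalog = gen$catalog)
  expect_equal(nrow(plane), 30)
  expect_equal(sum(table(plane$quadrant)), 30)

  rk <- rank_and_select(plane)
  expect_true(all(diff(rk$by_nhb$dnhb) <= 0))
  expect_true(all(diff(rk$by_ede$dede) <= 0))
  expect_setequal(rk$selected_nhb, plane$intervention[plane$dnhb > 0])

  # all-negative plane -> both selected sets empty
  neg <- plane
  neg$dnhb <- -abs(neg$dnhb)
  neg$dede <- -abs(neg$dede)
  rk_neg <- rank_and_select(neg)
  expect_length(rk_neg$selected_nhb, 0)
  expect_length(rk_neg$selected_ede, 0)

  # an intervention giving much to the poorest but with negative total NHB
  # is selected under EDE but not under NHB
  nhb <- c(4e5, 0, 0, 0, -4.5e5)
  post <- apply_intervention(base, nhb)
  pt <- equity_impact(base, post, aversion = 10, name = "equity_only")
  expect_lt(pt$dnhb, 0)
  expect_gt(pt$dede, 0)
  rk2 <- rank_and_select(pt)
  expect_equal(rk2$selected_ede, "equity_only")
  expect_length(rk2$selected_nhb, 0)
  expect_equal(rk2$disagreement, "equity_only")
})
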