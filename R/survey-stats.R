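#' Compute an asset-based wealth index and person-weighted quintiles
#'
#' The index is a simplified asset score: with equal positive weights on a
#' binary asset battery, a household scores
#' `100 * (assets owned) / (assets in battery)`, i.e. 0 when it owns none of
#' the assets and 100 when it owns all of them. Households are then ranked by
#' score (ties broken by household identifier) and partitioned into five
#' quintiles at the person-weighted 20/40/60/80 percentiles, so that each
#' quintile holds as near as possible one fifth of the *population*, not of
#' households.
#'
#' @param microdata A `dcea_microdata` list with an asset battery on
#'   `households`.
#' @return `microdata` with `wealth_score` and `wealth_quintile` columns added
#'   to `households`. Households with no asset data are excluded from scoring
#'   with a message reporting the count.
#' @export
compute_wealth_index <- function(microdata) {
  hh <- microdata$households
  asset_cols <- grep("^asset_", names(hh), value = TRUE)
  if (length(asset_cols) == 0L) {
    abort("no asset columns (`asset_*`) found on households.")
  }
  assets <- as.matrix(hh[asset_cols])
  complete <- stats::complete.cases(assets)
  if (any(!complete)) {
    inform(sprintf("excluding %d household(s) with no asset data from the wealth index.",
                   sum(!complete)))
  }
  hh$wealth_score <- ifelse(complete, 100 * rowMeans(assets), NA_real_)
  scored <- hh[complete, ]
  ord <- order(scored$wealth_score, scored$household_id)
  persons_per_hh <- scored$size %||%
    as.numeric(table(factor(microdata$persons$household_id,
                            levels = scored$household_id)))
  w <- persons_per_hh[ord]
  cum_mid <- cumsum(w) - w / 2
  q <- 1L + findInterval(cum_mid / sum(w), c(0.2, 0.4, 0.6, 0.8))
  hh$wealth_quintile <- NA_integer_
  hh$wealth_quintile[match(scored$household_id[ord], hh$household_id)] <- q
  microdata$households <- hh
  microdata
}

# Internal: person-level table with the grouping variable for a dimension.
person_groups <- function(microdata, dimension = c("wealth", "residence")) {
  dimension <- match.arg(dimension)
  hh <- microdata$households
  if (dimension == "wealth" && is.null(hh$wealth_quintile)) {
    abort("wealth quintiles not assigned; run `compute_wealth_index()` first.")
  }
  p <- microdata$persons
  i <- match(p$household_id, hh$household_id)
  if (dimension == "wealth") {
    labs <- c("poorest", "poorer", "middle", "richer", "richest")
    p$group <- factor(labs[hh$wealth_quintile[i]], levels = labs)
  } else {
    p$group <- factor(hh$residence[i], levels = c("rural", "urban"))
  }
  p
}

#' Estimate per-subgroup prevalence shares for one disease
#'
#' The share for subgroup g is the number of survey-reported cases of the
#' disease in g divided by the total reported cases, so the vector sums to 1.
#'
#' @param microdata Microdata with wealth quintiles assigned.
#' @param disease_code Disease code as reported in `persons$disease`.
#' @param dimension `"wealth"` (default) or `"residence"`.
#' @return Named numeric share vector (a `prevalence_share`); all-`NA` with a
#'   warning if no cases were reported.
#' @export
estimate_prevalence_shares <- function(microdata, disease_code,
                                       dimension = "wealth") {
  p <- person_groups(microdata, dimension)
  cases <- tapply(!is.na(p$disease) & p$disease == disease_code, p$group, sum)
  cases[is.na(cases)] <- 0
  if (sum(cases) == 0) {
    warn(sprintf("no reported cases of '%s'; prevalence shares are missing.",
                 disease_code))
    return(setNames(rep(NA_real_, nlevels(p$group)), levels(p$group)))
  }
  setNames(as.numeric(cases) / sum(cases), levels(p$group))
}

#' Estimate per-subgroup uptake for one disease
#'
#' Uptake in subgroup g is the number of cases in g that sought care divided
#' by the number of cases in g. Subgroups with zero cases get `NA` (to be
#' imputed); other entries are computed.
#'
#' @inheritParams estimate_prevalence_shares
#' @return Named numeric vector of uptake rates in \[0, 1\] (with `NA` where
#'   undefined).
#' @export
estimate_uptake <- function(microdata, disease_code, dimension = "wealth") {
  p <- person_groups(microdata, dimension)
  is_case <- !is.na(p$disease) & p$disease == disease_code
  cases <- tapply(is_case, p$group, sum)
  used <- tapply(is_case & p$care_sought, p$group, sum)
  cases[is.na(cases)] <- 0; used[is.na(used)] <- 0
  out <- as.numeric(ifelse(cases > 0, used / cases, NA_real_))
  setNames(out, levels(p$group))
}

#' Estimate opportunity-cost shares from public/church care episodes
#'
#' The distribution of health opportunity cost is proxied by the
#' socioeconomic distribution of healthcare utilization at public (government
#' or church-based) providers across all reported disease: the share for
#' subgroup g is its number of public-provider care episodes divided by the
#' total public-provider episodes. Episodes at other providers enter neither
#' numerator nor denominator.
#'
#' @inheritParams estimate_prevalence_shares
#' @return Named numeric share vector summing to 1.
#' @export
estimate_opportunity_cost_shares <- function(microdata, dimension = "wealth") {
  p <- person_groups(microdata, dimension)
  pub <- p$care_sought & !is.na(p$provider) & p$provider == "public"
  eps <- tapply(pub, p$group, sum)
  eps[is.na(eps)] <- 0
  if (sum(eps) == 0) {
    abort("no public/church care episodes; cannot estimate opportunity-cost shares.")
  }
  setNames(as.numeric(eps) / sum(eps), levels(p$group))
}

#' Impute wholly missing prevalence-share vectors
#'
#' Interventions with no observed prevalence distribution receive the
#' element-wise mean of the observed distributions, renormalized to sum to 1,
#' and are flagged `imputed`.
#'
#' @param prevalence Long share tibble (as from [read_share_table()]) of kind
#'   `prevalence_share`; a vector is "missing" when all its entries are `NA`.
#' @return The completed share tibble.
#' @export
impute_missing_prevalence <- function(prevalence) {
  wide <- tidyr::pivot_wider(prevalence, id_cols = "intervention",
                             names_from = "subgroup", values_from = "value")
  vals <- as.matrix(wide[-1])
  observed <- rowSums(!is.na(vals)) > 0
  if (!any(observed)) abort("all prevalence vectors are missing; nothing to impute from.")
  mean_vec <- colMeans(vals[observed, , drop = FALSE])
  mean_vec <- mean_vec / sum(mean_vec)
  out <- prevalence
  miss_names <- wide$intervention[!observed]
  fill <- out$intervention %in% miss_names
  out$value[fill] <- mean_vec[as.integer(out$subgroup[fill])]
  out$imputed <- out$imputed | fill
  out
}

#' Impute missing uptake entries with subgroup mean uptake
#'
#' Missing uptake entries (including wholly missing interventions) are filled
#' with the mean uptake observed for that subgroup across all interventions;
#' observed entries are kept. Downstream, utilization is eligible population
#' times prevalence share times the (completed) uptake.
#'
#' @param uptake Long share tibble of kind `uptake_rate`.
#' @return The completed share tibble with filled entries flagged `imputed`.
#' @export
impute_missing_uptake <- function(uptake) {
  means <- tapply(uptake$value, uptake$subgroup, mean, na.rm = TRUE)
  if (any(is.nan(means))) {
    abort(sprintf("no observed uptake anywhere for subgroup(s): %s.",
                  paste(names(means)[is.nan(means)], collapse = ", ")))
  }
  fill <- is.na(uptake$value)
  out <- uptake
  out$value[fill] <- as.numeric(means[as.character(out$subgroup[fill])])
  out$imputed <- out$imputed | fill
  out
}

#' Estimate all Stage-1 share inputs from microdata
#'
#' Convenience wrapper: assigns wealth quintiles, estimates prevalence shares
#' and uptake for every disease in the microdata, applies the imputation
#' rules, and estimates the population-wide opportunity-cost shares.
#'
#' @param microdata A complete `dcea_microdata` list.
#' @param dimension `"wealth"` or `"residence"`.
#' @return A list with long tibbles `prevalence`, `uptake` (one row set per
#'   disease code) and the `oc_shares` vector.
#' @export
estimate_shares <- function(microdata, dimension = "wealth") {
  md <- compute_wealth_index(microdata)
  codes <- sort(unique(stats::na.omit(md$persons$disease)))
  scheme <- if (dimension == "wealth") wealth_quintile_scheme() else residence_scheme()
  prev <- new_share_table(codes,
                          t(sapply(codes, function(d)
                            estimate_prevalence_shares(md, d, dimension))),
                          scheme, "prevalence_share")
  upt <- new_share_table(codes,
                         t(sapply(codes, function(d)
                           estimate_uptake(md, d, dimension))),
                         scheme, "uptake_rate")
  list(
    prevalence = impute_missing_prevalence(prev),
    uptake = impute_missing_uptake(upt),
    oc_shares = estimate_opportunity_cost_shares(md, dimension)
  )
}
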