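#' Allocate an eligible population over subgroups
#'
#' Splits an intervention's total eligible population A over subgroups in
#' proportion to the prevalence shares D: `eligible_g = A * D_g`, which sums
#' back to A.
#'
#' @param eligible_population Total eligible persons per year (A).
#' @param prevalence Prevalence share vector D (sums to 1, no missing values).
#' @return Per-subgroup eligible counts.
#' @examples
#' allocate_eligible(521300, c(0.36, 0.16, 0.23, 0.13, 0.12))
#' @export
allocate_eligible <- function(eligible_population, prevalence) {
  check_scalar_number(eligible_population, "eligible_population", min = 0)
  if (anyNA(prevalence)) {
    abort("prevalence shares contain missing values; impute them first (see `impute_missing_prevalence()`).")
  }
  eligible_population * prevalence
}

#' Per-subgroup direct health benefit
#'
#' Direct DALYs averted in subgroup g at current uptake:
#' `A * B * D_g * E_g`, with the same benefit per use B for every subgroup
#' (equal efficacy across socioeconomic groups is assumed).
#'
#' @inheritParams allocate_eligible
#' @param benefit_per_use Incremental DALYs averted per use (B).
#' @param uptake Uptake rate vector E, entries in \[0, 1\].
#' @return Per-subgroup DALYs averted.
#' @examples
#' direct_benefit_distribution(521300, 0.14, c(0.36, 0.16, 0.23, 0.13, 0.12),
#'                             c(0.48, 0.39, 0.46, 0.49, 0.43))
#' @export
direct_benefit_distribution <- function(eligible_population, benefit_per_use,
                                        prevalence, uptake) {
  if (anyNA(uptake) || any(uptake < 0) || any(uptake > 1)) {
    abort("uptake rates must all lie in [0, 1] with no missing values.")
  }
  allocate_eligible(eligible_population, prevalence) * benefit_per_use * uptake
}

#' Per-subgroup health opportunity cost
#'
#' The total incremental cost is converted to forgone DALYs at the marginal
#' productivity of health expenditure k (USD per DALY) and distributed over
#' subgroups by the opportunity-cost shares F:
#' `oc_g = F_g * total_cost / k`.
#'
#' @param total_incremental_cost Total incremental cost in USD (>= 0).
#' @param oc An [oc_model()] (holds k and F).
#' @return Per-subgroup DALYs forgone, summing to `total_cost / k`.
#' @examples
#' m <- oc_model(61, c(0.23, 0.22, 0.20, 0.19, 0.16), wealth_quintile_scheme())
#' opportunity_cost_distribution(809318, m)
#' @export
opportunity_cost_distribution <- function(total_incremental_cost, oc) {
  check_scalar_number(total_incremental_cost, "total_incremental_cost", min = 0)
  if (!inherits(oc, "oc_model")) abort("`oc` must be an `oc_model()`.")
  oc$shares * total_incremental_cost / oc$dollars_per_daly
}

#' Total incremental cost of an intervention
#'
#' Three costing conventions are supported: `per_eligible` charges the unit
#' cost for every eligible person (`A * C`); `per_treated` charges it only
#' for delivered services (`A * C * sum(D_g * E_g)`), the package default;
#' `fixed` uses a supplied total verbatim (needed to reproduce published
#' worked examples whose printed totals follow neither formula).
#'
#' @inheritParams direct_benefit_distribution
#' @param unit_cost Incremental cost per use in USD (C).
#' @param mode Costing convention.
#' @param fixed Total cost in USD, required when `mode = "fixed"`.
#' @return Total cost in USD.
#' @export
total_cost <- function(eligible_population, unit_cost,
                       prevalence = NULL, uptake = NULL,
                       mode = c("per_treated", "per_eligible", "fixed"),
                       fixed = NULL) {
  mode <- match.arg(mode)
  switch(mode,
    per_eligible = eligible_population * unit_cost,
    per_treated = {
      if (is.null(prevalence) || is.null(uptake)) {
        abort("`per_treated` mode needs `prevalence` and `uptake`.")
      }
      eligible_population * unit_cost * sum(prevalence * uptake)
    },
    fixed = {
      if (is.null(fixed)) abort("`fixed` mode needs a supplied `fixed` total cost.")
      check_scalar_number(fixed, "fixed", min = 0)
      fixed
    }
  )
}

#' Combine direct benefit and opportunity cost into net health benefit
#'
#' `nhb_g = benefit_g - oc_g`; the population total is the sum and may be
#' negative. When the total is positive the per-subgroup shares of net health
#' benefit are also reported.
#'
#' @param direct Per-subgroup direct benefit (DALYs averted).
#' @param oc_dalys Per-subgroup opportunity cost (DALYs forgone).
#' @param scheme A [subgroup_scheme()].
#' @param name Intervention name carried into the result.
#' @return A tibble of class `dcea_impact` with one row per subgroup and
#'   columns `direct_benefit`, `opportunity_cost`, `net_benefit`, `nhb_share`.
#' @export
net_benefit_distribution <- function(direct, oc_dalys, scheme,
                                     name = "intervention") {
  check_subgroup_vector(direct, scheme, "direct")
  check_subgroup_vector(oc_dalys, scheme, "oc_dalys")
  nhb <- direct - oc_dalys
  out <- tibble::tibble(
    intervention = name,
    subgroup = scheme$subgroup,
    direct_benefit = as.numeric(direct),
    opportunity_cost = as.numeric(oc_dalys),
    net_benefit = as.numeric(nhb),
    nhb_share = if (sum(nhb) > 0) as.numeric(nhb) / sum(nhb) else NA_real_
  )
  class(out) <- c("dcea_impact", class(out))
  out
}

# Internal: full Stage-1 computation for one intervention.
impact_one <- function(record, prevalence, uptake, oc,
                       cost_mode = "per_treated", fixed_cost = NULL,
                       scheme = oc$scheme) {
  A <- record$eligible_population
  B <- record$incremental_benefit
  C <- record$incremental_cost
  eligible <- allocate_eligible(A, prevalence)
  treated <- eligible * uptake
  direct <- direct_benefit_distribution(A, B, prevalence, uptake)
  tc <- total_cost(A, C, prevalence, uptake, mode = cost_mode, fixed = fixed_cost)
  ocd <- opportunity_cost_distribution(tc, oc)
  res <- net_benefit_distribution(direct, ocd, scheme, name = record$name)
  res$eligible <- as.numeric(eligible)
  res$treated <- as.numeric(treated)
  attr(res, "total_cost") <- tc
  res[, c("intervention", "subgroup", "eligible", "treated",
          "direct_benefit", "opportunity_cost", "net_benefit", "nhb_share")]
}

#' Stage 1: distributional impact of a catalog of interventions
#'
#' For every intervention, allocates the eligible population by prevalence
#' share, computes direct DALYs averted at current uptake, converts the
#' incremental cost into distributed health opportunity cost, and nets the
#' two into the per-subgroup net health benefit.
#'
#' @param catalog Intervention tibble (see [read_intervention_table()]).
#' @param prevalence,uptake Long share tibbles keyed by `intervention`
#'   (complete; run the imputation first).
#' @param oc An [oc_model()].
#' @param cost_mode Costing convention, see [total_cost()].
#' @param fixed_costs Optional named vector of fixed totals (USD) when
#'   `cost_mode = "fixed"`.
#' @param scenario `"current"` (observed uptake) or `"full_coverage"`
#'   (uptake set to 1 everywhere with cost scaled accordingly).
#' @return A `dcea_impact` tibble, one row per intervention and subgroup.
#' @export
distributional_impact <- function(catalog, prevalence, uptake, oc,
                                  cost_mode = c("per_treated", "per_eligible", "fixed"),
                                  fixed_costs = NULL,
                                  scenario = c("current", "full_coverage")) {
  cost_mode <- match.arg(cost_mode)
  scenario <- match.arg(scenario)
  scheme <- oc$scheme
  rows <- purrr::map(seq_len(nrow(catalog)), function(i) {
    rec <- catalog[i, ]
    d <- share_values(prevalence, rec$name, scheme)
    e <- share_values(uptake, rec$name, scheme)
    fx <- if (!is.null(fixed_costs)) unname(fixed_costs[rec$name]) else NULL
    if (scenario == "full_coverage") {
      full_coverage_scenario(rec, d, e, oc, cost_mode = cost_mode,
                             fixed_cost = fx)
    } else {
      impact_one(rec, d, e, oc, cost_mode = cost_mode, fixed_cost = fx)
    }
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("dcea_impact", class(out))
  out
}

#' Full-coverage scenario for one intervention
#'
#' Recomputes the Stage-1 distribution with uptake set to 1 in every subgroup
#' ("if utilization were increased to 100%"). The total cost scales with the
#' costing convention: `per_treated` and `per_eligible` both become `A * C`;
#' a `fixed` total is scaled by the ratio of full to current service volume.
#'
#' @param record One-row intervention tibble.
#' @param prevalence,uptake Share vectors for the record.
#' @param oc An [oc_model()].
#' @inheritParams distributional_impact
#' @param fixed_cost Fixed current-uptake total cost (USD), `fixed` mode only.
#' @return A `dcea_impact` tibble for the record.
#' @export
full_coverage_scenario <- function(record, prevalence, uptake, oc,
                                   cost_mode = "per_treated",
                                   fixed_cost = NULL) {
  e_full <- rep(1, length(prevalence))
  fx <- fixed_cost
  if (cost_mode == "fixed") {
    if (is.null(fx)) abort("`fixed` mode needs a supplied `fixed_cost`.")
    fx <- fx * sum(prevalence) / sum(prevalence * uptake)
  }
  impact_one(record, prevalence, e_full, oc, cost_mode = cost_mode,
             fixed_cost = fx)
}

#' Totals of a distributional impact table
#'
#' @param impact A `dcea_impact` tibble.
#' @return One row per intervention with summed benefit, opportunity cost and
#'   net health benefit.
#' @export
impact_totals <- function(impact) {
  dplyr::summarise(
    dplyr::group_by(impact, .data$intervention),
    direct_benefit = sum(.data$direct_benefit),
    opportunity_cost = sum(.data$opportunity_cost),
    net_benefit = sum(.data$net_benefit),
    .groups = "drop"
  )
}
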