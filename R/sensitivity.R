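#' Tilt a five-quintile share vector towards the poor
#'
#' Multiplies the poorest and poorer entries by `factor_low` (default 1.1)
#' and the richer and richest entries by `factor_high` (default 0.9), leaving
#' the middle quintile unchanged. Sum-constrained kinds (prevalence and
#' opportunity-cost shares) are renormalized to sum to 1; uptake rates are
#' clipped to \[0, 1\] (with a warning) and not renormalized. An
#' un-renormalized variant for sum-constrained kinds is available via
#' `renormalize = FALSE`.
#'
#' @param shares Named or plain numeric five-quintile vector.
#' @param kind Share kind, see [validate_share_vector()].
#' @param factor_low,factor_high Multipliers for the two poorest / two
#'   richest quintiles.
#' @param renormalize Renormalize sum-constrained kinds (default `TRUE`).
#' @return The transformed vector.
#' @examples
#' tilt_shares(rep(0.2, 5), "prevalence_share")
#' @export
tilt_shares <- function(shares, kind, factor_low = 1.1, factor_high = 0.9,
                        renormalize = TRUE) {
  kind <- match.arg(kind, share_kinds)
  if (length(shares) != 5L) {
    abort("tilts are defined for five wealth quintiles (poorest to richest).")
  }
  out <- shares * c(factor_low, factor_low, 1, factor_high, factor_high)
  if (kind == "uptake_rate") {
    if (any(out > 1, na.rm = TRUE)) {
      warn("tilted uptake exceeded 1 and was clipped.")
    }
    out <- pmin(out, 1)
  } else if (renormalize) {
    out <- out / sum(out)
  }
  out
}

#' Equalized share vector
#'
#' Sensitivity scenarios that remove the socioeconomic signal: prevalence and
#' opportunity-cost shares become equal fifths; uptake becomes the
#' population-average uptake (total utilization over total cases, i.e. the
#' prevalence-weighted mean of the subgroup uptakes) replicated to all
#' quintiles.
#'
#' @param kind Share kind.
#' @param n_groups Number of subgroups (default 5).
#' @param uptake,prevalence Current vectors, needed for `uptake_rate` to form
#'   the population average.
#' @return The equalized vector.
#' @export
equalize_shares <- function(kind, n_groups = 5L, uptake = NULL,
                            prevalence = NULL) {
  kind <- match.arg(kind, share_kinds)
  if (kind == "uptake_rate") {
    if (is.null(uptake) || is.null(prevalence)) {
      abort("equalizing uptake needs the current `uptake` and `prevalence`.")
    }
    rep(sum(prevalence * uptake) / sum(prevalence), length(uptake))
  } else {
    rep(1 / n_groups, n_groups)
  }
}

#' Declare a sensitivity scenario
#'
#' A scenario is a named list of transforms, each touching a disjoint input:
#' `prevalence` (`"equal"`, `"tilt_poor"`), `uptake` (`"equal"`,
#' `"tilt_poor"`), `oc_shares` (`"equal"`, `"tilt_poor"`), `oc_rate`
#' (replacement USD/DALY), `baseline_mode` (`"children_only"`), `aversion`
#' (replacement epsilon).
#'
#' @param name Scenario label.
#' @param ... Transforms as named arguments.
#' @return A list of class `dcea_scenario`.
#' @examples
#' scenario("Equal uptake", uptake = "equal")
#' scenario("Opp. cost = $37/DALY", oc_rate = 37)
#' @export
scenario <- function(name, ...) {
  tr <- list(...)
  known <- c("prevalence", "uptake", "oc_shares", "oc_rate", "baseline_mode",
             "aversion")
  bad <- setdiff(names(tr), known)
  if (length(bad) > 0L) {
    abort(sprintf("unknown scenario transform(s): %s.", paste(bad, collapse = ", ")))
  }
  structure(c(list(name = name), tr), class = "dcea_scenario")
}

#' The standard sensitivity grid
#'
#' Base case plus the eleven standard scenarios: equal / more-unequal
#' prevalence, equal / more-unequal uptake, opportunity-cost rates of $37 and
#' $116 per DALY, equal / more-unequal opportunity-cost shares, a
#' children-only mortality baseline, and aversion 2 and 25.
#'
#' @return A list of [scenario()] objects.
#' @export
default_scenarios <- function() {
  list(
    scenario("Base case"),
    scenario("Equal prevalence", prevalence = "equal"),
    scenario("More unequal prevalence", prevalence = "tilt_poor"),
    scenario("Equal uptake", uptake = "equal"),
    scenario("More unequal uptake", uptake = "tilt_poor"),
    scenario("Opp. cost = $37/DALY", oc_rate = 37),
    scenario("Opp. cost = $116/DALY", oc_rate = 116),
    scenario("Equal opp. cost", oc_shares = "equal"),
    scenario("More unequal opp. cost", oc_shares = "tilt_poor"),
    scenario("Child mortality baseline", baseline_mode = "children_only"),
    scenario("Low inequality aversion (eps = 2)", aversion = 2),
    scenario("High inequality aversion (eps = 25)", aversion = 25)
  )
}

# Apply a share transform to every intervention row of a long share table.
transform_share_table <- function(tbl, what, kind, scheme) {
  wide <- tidyr::pivot_wider(tbl, id_cols = "intervention",
                             names_from = "subgroup", values_from = "value")
  vals <- as.matrix(wide[-1])
  for (i in seq_len(nrow(vals))) {
    v <- vals[i, ]
    vals[i, ] <- switch(what,
      equal = equalize_shares(kind, n_groups = length(v), uptake = v,
                              prevalence = if (kind == "uptake_rate")
                                attr(tbl, "prevalence_row")[[wide$intervention[i]]]
                              else NULL),
      tilt_poor = tilt_shares(v, kind),
      abort(sprintf("unknown transform '%s'.", what))
    )
  }
  new_share_table(wide$intervention, vals, scheme, kind,
                  imputed = tbl$imputed[match(wide$intervention, tbl$intervention)])
}

#' Run a suite of sensitivity scenarios
#'
#' Re-runs the Stage 1-3 pipeline once per scenario, each starting from the
#' untouched base-case inputs (transforms are pure). Aggregate results mirror
#' the standard sensitivity grid: package-level dNHB and dEDE over the
#' current-package interventions, the inequality impact, the four quadrant
#' counts over the full catalog, and counts of NHB-, EDE- and
#' inequality-improving interventions.
#'
#' @param catalog Intervention tibble.
#' @param prevalence,uptake Completed long share tibbles.
#' @param baseline A `dcea_hale` distribution for the base mortality mode;
#'   when `microdata` is supplied, `baseline_mode` scenarios rebuild it.
#' @param config A [dcea_config()].
#' @param scenarios List of [scenario()] objects; defaults to
#'   [default_scenarios()]. The base case is always run first.
#' @param microdata Optional microdata for `baseline_mode` scenarios.
#' @return A list with `grid` (a tibble of class `dcea_scenario_grid`, one
#'   row per scenario) and `planes` (named list of `dcea_equity_plane`
#'   tibbles).
#' @export
run_scenario_suite <- function(catalog, prevalence, uptake, baseline, config,
                               scenarios = default_scenarios(),
                               microdata = NULL) {
  if (length(scenarios) == 0L || scenarios[[1]]$name != "Base case") {
    scenarios <- c(list(scenario("Base case")), scenarios)
  }
  scheme <- config$scheme
  # stash per-intervention prevalence rows so uptake equalization can weight
  prev_rows <- split(prevalence$value, prevalence$intervention)
  run_one <- function(sc) {
    prev <- prevalence
    upt <- uptake
    oc <- config$oc
    aversion <- config$aversion
    base <- baseline
    if (!is.null(sc$prevalence)) {
      prev <- transform_share_table(prev, sc$prevalence, "prevalence_share", scheme)
    }
    if (!is.null(sc$uptake)) {
      attr(upt, "prevalence_row") <- prev_rows
      upt <- transform_share_table(upt, sc$uptake, "uptake_rate", scheme)
    }
    if (!is.null(sc$oc_rate)) {
      oc <- oc_model(sc$oc_rate, oc$shares, scheme)
    }
    if (!is.null(sc$oc_shares)) {
      new_f <- switch(sc$oc_shares,
        equal = equalize_shares("opportunity_cost_share", n_subgroups(scheme)),
        tilt_poor = tilt_shares(oc$shares, "opportunity_cost_share"),
        abort(sprintf("unknown oc_shares transform '%s'.", sc$oc_shares)))
      oc <- oc_model(oc$dollars_per_daly, new_f, scheme)
    }
    if (!is.null(sc$baseline_mode)) {
      if (is.null(microdata)) {
        abort("baseline_mode scenarios need `microdata` to rebuild the baseline.")
      }
      base <- baseline_hale(compute_wealth_index(microdata), scheme = scheme,
                            mode = sc$baseline_mode)
    }
    if (!is.null(sc$aversion)) aversion <- sc$aversion
    impact <- distributional_impact(catalog, prev, upt, oc,
                                    cost_mode = config$cost_mode)
    plane <- equity_plane(impact, base, aversion = aversion, catalog = catalog)
    ehp <- catalog$name[catalog$in_ehp]
    ehp_nhb <- dplyr::summarise(
      dplyr::group_by(impact[impact$intervention %in% ehp, ], .data$subgroup),
      net_benefit = sum(.data$net_benefit), .groups = "drop")
    post <- apply_intervention(base, ehp_nhb)
    pkg_point <- equity_impact(base, post, aversion = aversion,
                               name = "EHP package")
    tibble::tibble(
      scenario = sc$name,
      dnhb = pkg_point$dnhb,
      dede = pkg_point$dede,
      inequality_impact = pkg_point$inequality_impact,
      q1 = sum(plane$quadrant == "Q1 (+,+)"),
      q2 = sum(plane$quadrant == "Q2 (+,-)"),
      q3 = sum(plane$quadrant == "Q3 (-,+)"),
      q4 = sum(plane$quadrant == "Q4 (-,-)"),
      nhb_improving = sum(plane$dnhb > 0),
      ede_improving = sum(plane$dede > 0),
      inequality_improving = sum(plane$inequality_impact > 0),
      plane = list(plane)
    )
  }
  rows <- purrr::map(scenarios, run_one)
  grid <- dplyr::bind_rows(rows)
  planes <- grid$plane
  names(planes) <- grid$scenario
  grid$plane <- NULL
  class(grid) <- c("dcea_scenario_grid", class(grid))
  list(grid = grid, planes = planes)
}
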