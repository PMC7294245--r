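# Core Atkinson EDE on a grouped distribution: weights w sum to 1.
ede_value <- function(h, w, aversion) {
  if (abs(sum(w) - 1) > 1e-9) abort("weights must sum to 1.")
  if (aversion < 0) abort("`aversion` must be >= 0.")
  if (any(h <= 0) && aversion >= 1) {
    abort("all health values must be positive for aversion >= 1.")
  }
  # the power form loses precision as aversion -> 1; inside a small window
  # use the exact limit (weighted geometric mean)
  if (aversion == 0) {
    sum(w * h)
  } else if (abs(aversion - 1) < 1e-6) {
    exp(sum(w * log(h)))
  } else {
    sum(w * h^(1 - aversion))^(1 / (1 - aversion))
  }
}

#' Atkinson equally distributed equivalent (EDE) health
#'
#' The EDE is the uniform level of health society values equally to the
#' actual distribution, under inequality aversion `epsilon`:
#' `EDE = (sum_g w_g * h_g^(1-eps))^(1/(1-eps))`, evaluated over population
#' subgroups with population-share weights. `eps = 1` is the limiting
#' geometric mean and `eps = 0` returns the population mean. The Atkinson
#' index is `1 - EDE/mean`, and `mean - EDE` is the cost of inequality in
#' healthy years per person.
#'
#' @param data Data frame with one row per subgroup.
#' @param health Column with subgroup health (e.g. HALE in healthy years);
#'   unquoted name.
#' @param weight Column with population weights (normalized internally);
#'   unquoted name. For a `dcea_hale` input both default to `hale` and
#'   `weight`.
#' @param aversion Inequality-aversion parameter epsilon (>= 0; base case 10).
#' @return An object of class `dcea_ede`: list with `mean`, `ede`,
#'   `atkinson`, `cost_of_inequality`, `aversion`, and the input distribution.
#' @examples
#' hale <- data.frame(group = c("urban", "rural"),
#'                    hale = c(49.15, 53.18), weight = c(0.15, 0.85))
#' atkinson_ede(hale, hale, weight, aversion = 10)
#' @export
atkinson_ede <- function(data, health = hale, weight = weight, aversion = 10) {
  h <- dplyr::pull(data, {{ health }})
  w <- dplyr::pull(data, {{ weight }})
  w <- w / sum(w)
  m <- sum(w * h)
  ede <- ede_value(h, w, aversion)
  structure(list(
    mean = m, ede = ede, atkinson = 1 - ede / m,
    cost_of_inequality = m - ede, aversion = aversion,
    distribution = tibble::tibble(health = h, weight = w)
  ), class = "dcea_ede")
}

#' @export
print.dcea_ede <- function(x, ...) {
  cat(sprintf(
    "Atkinson EDE (aversion %.6g)\n  mean health: %.4f\n  EDE health:  %.4f\n  Atkinson index: %.6f\n  cost of inequality: %.4f per person\n",
    x$aversion, x$mean, x$ede, x$atkinson, x$cost_of_inequality))
  invisible(x)
}

#' @export
tidy.dcea_ede <- function(x, ...) {
  tibble::tibble(
    term = c("mean", "ede", "atkinson", "cost_of_inequality"),
    estimate = c(x$mean, x$ede, x$atkinson, x$cost_of_inequality)
  )
}

#' @export
glance.dcea_ede <- function(x, ...) {
  tibble::tibble(mean = x$mean, ede = x$ede, atkinson = x$atkinson,
                 cost_of_inequality = x$cost_of_inequality,
                 aversion = x$aversion, n_groups = nrow(x$distribution))
}

#' Add an intervention's net health benefit to a baseline HALE distribution
#'
#' Per-subgroup net health benefit in DALYs is converted to healthy years per
#' person (`nhb_g / population_g`) and added to the baseline HALE; negative
#' per-person changes are allowed (a subgroup can lose from an intervention
#' when its opportunity-cost share exceeds its benefit share).
#'
#' @param baseline A `dcea_hale` distribution (columns `subgroup`, `hale`,
#'   `population`, `weight`).
#' @param net_benefit Per-subgroup net health benefit in DALYs: a numeric
#'   vector in scheme order, or a `dcea_impact` table for one intervention.
#' @return The post-intervention `dcea_hale` distribution.
#' @export
apply_intervention <- function(baseline, net_benefit) {
  if (inherits(net_benefit, "data.frame")) {
    if ("intervention" %in% names(net_benefit) &&
        length(unique(net_benefit$intervention)) > 1L) {
      net_benefit <- dplyr::summarise(
        dplyr::group_by(net_benefit, .data$subgroup),
        net_benefit = sum(.data$net_benefit), .groups = "drop")
    }
    nhb <- net_benefit$net_benefit[match(as.character(baseline$subgroup),
                                         as.character(net_benefit$subgroup))]
  } else {
    nhb <- as.numeric(net_benefit)
  }
  if (length(nhb) != nrow(baseline) || anyNA(nhb)) {
    abort("`net_benefit` must supply one value per baseline subgroup.")
  }
  out <- baseline
  out$hale <- baseline$hale + nhb / baseline$population
  bad <- which(out$hale <= 0)
  if (length(bad) > 0L) {
    abort(sprintf("post-intervention HALE is non-positive for subgroup '%s'.",
                  as.character(out$subgroup[bad[1]])))
  }
  out
}

#' Equity impact of moving from a baseline to a post-intervention distribution
#'
#' Scales per-person changes to population DALYs: `dNHB` is the change in
#' mean health times the population, `dEDE` the change in EDE health times
#' the population, and the inequality impact is `dEDE - dNHB` — positive when
#' the intervention reduces inequality (its social value exceeds its raw
#' health gain), negative when it increases inequality. Quadrants are labelled
#' by the signs `(dNHB, inequality impact)`.
#'
#' @param baseline,post `dcea_hale` distributions on the same scheme.
#' @param aversion Inequality-aversion parameter.
#' @param total_population Defaults to the scheme population total.
#' @param name Intervention name carried into the result.
#' @return One-row tibble of class `dcea_equity_point`: `intervention`,
#'   `dnhb`, `dede`, `inequality_impact`, `quadrant`.
#' @export
equity_impact <- function(baseline, post, aversion = 10,
                          total_population = NULL, name = "intervention") {
  if (!identical(as.character(baseline$subgroup), as.character(post$subgroup))) {
    abort("baseline and post distributions must share the same subgroups.")
  }
  if (is.null(total_population)) total_population <- sum(baseline$population)
  w <- baseline$weight / sum(baseline$weight)
  dnhb <- total_population * (sum(w * post$hale) - sum(w * baseline$hale))
  dede <- total_population * (ede_value(post$hale, w, aversion) -
                                ede_value(baseline$hale, w, aversion))
  ineq <- dede - dnhb
  out <- tibble::tibble(
    intervention = name, dnhb = dnhb, dede = dede,
    inequality_impact = ineq,
    quadrant = quadrant_label(dnhb, ineq)
  )
  class(out) <- c("dcea_equity_point", class(out))
  out
}

quadrant_label <- function(dnhb, ineq) {
  dplyr::case_when(
    dnhb >= 0 & ineq >= 0 ~ "Q1 (+,+)",
    dnhb >= 0 & ineq < 0 ~ "Q2 (+,-)",
    dnhb < 0 & ineq >= 0 ~ "Q3 (-,+)",
    TRUE ~ "Q4 (-,-)"
  )
}

#' Place every intervention on the health equity impact plane
#'
#' Applies each intervention's net-health-benefit distribution to the
#' baseline HALE distribution and computes its population net health benefit,
#' EDE change and inequality impact.
#'
#' @param impact A `dcea_impact` table (Stage-1 output for a catalog).
#' @param baseline A `dcea_hale` distribution.
#' @param aversion Inequality-aversion parameter.
#' @param catalog Optional catalog tibble; when given, `in_ehp` is joined in.
#' @return A tibble of class `dcea_equity_plane`, one row per intervention.
#' @export
equity_plane <- function(impact, baseline, aversion = 10, catalog = NULL) {
  names_ <- unique(impact$intervention)
  pts <- purrr::map(names_, function(nm) {
    sub <- impact[impact$intervention == nm, ]
    post <- apply_intervention(baseline, sub)
    equity_impact(baseline, post, aversion = aversion, name = nm)
  })
  out <- dplyr::bind_rows(pts)
  if (!is.null(catalog)) {
    out <- dplyr::left_join(out, catalog[c("name", "in_ehp")],
                            by = c(intervention = "name"))
  }
  class(out) <- c("dcea_equity_plane", class(out))
  out
}

#' Rank interventions by net health benefit and by EDE change
#'
#' Produces the two priority orderings an equity-informed package design
#' compares: by population net health benefit and by EDE change (both
#' descending, ties broken by intervention name), the two selected sets
#' (positive dNHB vs positive dEDE), and their symmetric difference — the
#' interventions whose selection depends on whether inequality is valued.
#'
#' @param points A `dcea_equity_plane` tibble.
#' @return A list with `by_nhb`, `by_ede` (ordered tibbles), `selected_nhb`,
#'   `selected_ede` (character vectors) and `disagreement`.
#' @export
rank_and_select <- function(points) {
  if (nrow(points) < 1L) abort("need at least one equity-plane point.")
  by_nhb <- points[order(-points$dnhb, points$intervention), ]
  by_ede <- points[order(-points$dede, points$intervention), ]
  sel_a <- points$intervention[points$dnhb > 0]
  sel_b <- points$intervention[points$dede > 0]
  list(
    by_nhb = by_nhb, by_ede = by_ede,
    selected_nhb = sort(sel_a), selected_ede = sort(sel_b),
    disagreement = sort(c(setdiff(sel_a, sel_b), setdiff(sel_b, sel_a)))
  )
}
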