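#' Inputs of the rotavirus-vaccination worked example
#'
#' The published worked example for rotavirus vaccination of children under
#' one: eligible population A = 521,300; incremental benefit B = 0.14 DALYs
#' per use; incremental cost C = $0.69 per use; printed total cost $809,318
#' (used verbatim in `fixed` cost mode — note it matches neither `A*C` nor
#' `A*C*sum(D*E)`); survey prevalence shares D, uptake E, opportunity-cost
#' shares F; marginal productivity k = $61 per DALY.
#'
#' @return A list with the example's inputs, including the wealth scheme.
#' @export
box1_inputs <- function() {
  scheme <- wealth_quintile_scheme()
  list(
    record = tibble::tibble(name = "Rotavirus vaccination",
                            eligible_population = 521300,
                            incremental_cost = 0.69,
                            incremental_benefit = 0.14,
                            in_ehp = TRUE),
    prevalence = setNames(c(0.36, 0.16, 0.23, 0.13, 0.12), scheme_labels(scheme)),
    uptake = setNames(c(0.48, 0.39, 0.46, 0.49, 0.43), scheme_labels(scheme)),
    oc = oc_model(61, c(0.23, 0.22, 0.20, 0.19, 0.16), scheme),
    fixed_total_cost = 809318,
    scheme = scheme
  )
}

# Published reference cells for the worked example, rounded as printed.
box1_reference <- function() {
  tibble::tibble(
    row = c("full_coverage_benefit", "current_benefit", "opportunity_cost",
            "net_benefit", "nhb_share"),
    poorest = c(26274, 12611, 3052, 9560, 0.48),
    poorer = c(11677, 4554, 2919, 1635, 0.08),
    middle = c(16786, 7721, 2654, 5068, 0.25),
    richer = c(9488, 4649, 2521, 2128, 0.11),
    richest = c(8758, 3766, 2123, 1643, 0.08),
    total = c(72982, 33302, 13268, 20034, 1.00)
  )
}

#' Run the rotavirus worked example and compare against the published table
#'
#' Recomputes every row of the worked example with the Stage-1 pipeline in
#' `fixed` cost mode, rounds as the published table does (half-up to whole
#' DALYs, two decimals for shares), and flags any cell that disagrees with
#' the published value. Also reports the `per_eligible` total cost `A*C`,
#' which exposes the published table's internal total-cost inconsistency.
#'
#' @return A list with `impact` (the full-precision `dcea_impact` tibble),
#'   `comparison` (long tibble: row, subgroup, computed, published, match),
#'   `full_coverage` (full-precision full-coverage impact), and `total_cost`
#'   (tibble of the three costing conventions for these inputs).
#' @examples
#' res <- run_box1_fixture()
#' all(res$comparison$match)
#' @export
run_box1_fixture <- function() {
  inp <- box1_inputs()
  cur <- impact_one(inp$record, inp$prevalence, inp$uptake, inp$oc,
                    cost_mode = "fixed", fixed_cost = inp$fixed_total_cost)
  full <- full_coverage_scenario(inp$record, inp$prevalence, inp$uptake,
                                 inp$oc, cost_mode = "fixed",
                                 fixed_cost = inp$fixed_total_cost)
  labs <- c(scheme_labels(inp$scheme), "total")
  computed <- rbind(
    full_coverage_benefit = round_half_up(c(full$direct_benefit,
                                            sum(full$direct_benefit))),
    current_benefit = round_half_up(c(cur$direct_benefit,
                                      sum(cur$direct_benefit))),
    opportunity_cost = round_half_up(c(cur$opportunity_cost,
                                       sum(cur$opportunity_cost))),
    net_benefit = round_half_up(c(cur$net_benefit, sum(cur$net_benefit))),
    nhb_share = round_half_up(c(cur$net_benefit / sum(cur$net_benefit), 1), 2)
  )
  colnames(computed) <- labs
  ref <- box1_reference()
  comparison <- tidyr::pivot_longer(ref, -"row", names_to = "subgroup",
                                    values_to = "published")
  comparison$computed <- as.numeric(t(computed[ref$row, labs]))
  comparison$match <- comparison$computed == comparison$published
  comparison <- comparison[c("row", "subgroup", "computed", "published", "match")]
  costs <- tibble::tibble(
    mode = c("fixed", "per_eligible", "per_treated"),
    total_cost = c(
      inp$fixed_total_cost,
      total_cost(inp$record$eligible_population, inp$record$incremental_cost,
                 mode = "per_eligible"),
      total_cost(inp$record$eligible_population, inp$record$incremental_cost,
                 inp$prevalence, inp$uptake, mode = "per_treated")
    )
  )
  list(impact = cur, comparison = comparison, full_coverage = full,
       total_cost = costs)
}
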