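share_kinds <- c("prevalence_share", "uptake_rate", "opportunity_cost_share")

#' Validate a per-subgroup share vector
#'
#' Three kinds of per-subgroup vectors drive the distributional model:
#' prevalence shares (the proportion of an intervention's eligible cases in
#' each subgroup, symbolically D), uptake rates (the proportion of eligible
#' cases in each subgroup that use the service, E), and opportunity-cost
#' shares (the proportion of forgone health borne by each subgroup, F).
#' Prevalence and opportunity-cost shares must be nonnegative and sum to one;
#' uptake rates must each lie in \[0, 1\]. Missing values (`NA`) are allowed —
#' they mark entries awaiting imputation — and suspend the sum check.
#'
#' @param values Numeric vector, one entry per subgroup of `scheme`; `NA`
#'   marks missing.
#' @param scheme A [subgroup_scheme()].
#' @param kind One of `"prevalence_share"`, `"uptake_rate"`,
#'   `"opportunity_cost_share"`.
#' @param tol Tolerance on the sum-to-one constraint.
#'
#' @return `values`, named by subgroup, invisibly classed by kind; errors on
#'   violation.
#' @examples
#' sch <- wealth_quintile_scheme()
#' validate_share_vector(c(0.36, 0.16, 0.23, 0.13, 0.12), sch, "prevalence_share")
#' @export
validate_share_vector <- function(values, scheme, kind, tol = 1e-6) {
  kind <- match.arg(kind, share_kinds)
  check_subgroup_vector(values, scheme)
  obs <- values[!is.na(values)]
  if (any(obs < 0)) {
    abort(sprintf("%s values must be nonnegative.", kind))
  }
  if (kind == "uptake_rate" && any(obs > 1)) {
    abort("uptake_rate values must lie in [0, 1].")
  }
  if (kind != "uptake_rate" && length(obs) == length(values) &&
      !near_sum(obs, 1, tol)) {
    abort(sprintf("%s values must sum to 1 (sum = %.9f).", kind, sum(obs)))
  }
  invisible(setNames(as.numeric(values), scheme_labels(scheme)))
}

# Internal: long share tibble constructor used by readers and estimators.
new_share_table <- function(intervention, values_by_row, scheme, kind,
                            imputed = FALSE) {
  labs <- scheme_labels(scheme)
  n <- length(intervention)
  tibble::tibble(
    intervention = rep(intervention, each = length(labs)),
    subgroup = factor(rep(labs, n), levels = labs),
    value = as.numeric(t(values_by_row)),
    kind = kind,
    imputed = rep(imputed, each = length(labs), length.out = n * length(labs))
  )
}

# Internal: one intervention's share values as a named vector in scheme order.
share_values <- function(share_tbl, name, scheme) {
  rows <- share_tbl[share_tbl$intervention == name, , drop = FALSE]
  if (nrow(rows) == 0L) {
    abort(sprintf("no share row for intervention '%s'.", name))
  }
  v <- rows$value[match(scheme_labels(scheme), as.character(rows$subgroup))]
  setNames(v, scheme_labels(scheme))
}
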