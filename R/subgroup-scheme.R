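#' Define an ordered socioeconomic subgroup scheme
#'
#' A subgroup scheme names the equity-relevant population groups over which
#' distributions are evaluated, ordered from most to least disadvantaged, with
#' the number of persons in each group. Two schemes cover the common cases:
#' five wealth-asset-index quintiles and urban/rural residence.
#'
#' @param dimension Name of the stratifying dimension, e.g. `"wealth"` or
#'   `"residence"`.
#' @param labels Character vector of unique subgroup names ordered from most
#'   to least disadvantaged (e.g. `"poorest"` first).
#' @param population_counts Positive number of persons per subgroup, same
#'   length as `labels`.
#'
#' @return A tibble of class `subgroup_scheme` with columns `subgroup`,
#'   `population`, and `share` (population share), carrying the dimension name
#'   as an attribute.
#' @examples
#' wealth_quintile_scheme(17.5e6)
#' residence_scheme(17.5e6, urban_share = 0.15)
#' @export
subgroup_scheme <- function(dimension, labels, population_counts) {
  if (!is.character(labels) || anyDuplicated(labels) > 0L || length(labels) < 2L) {
    abort("`labels` must be at least two unique subgroup names.")
  }
  if (length(population_counts) != length(labels) || any(population_counts <= 0)) {
    abort("`population_counts` must be positive, one per label.")
  }
  out <- tibble::tibble(
    subgroup = factor(labels, levels = labels),
    population = as.numeric(population_counts),
    share = as.numeric(population_counts) / sum(population_counts)
  )
  structure(out, dimension = dimension,
            class = c("subgroup_scheme", class(out)))
}

#' @rdname subgroup_scheme
#' @param total_population Total persons across all subgroups.
#' @export
wealth_quintile_scheme <- function(total_population = 17.5e6) {
  subgroup_scheme(
    "wealth",
    c("poorest", "poorer", "middle", "richer", "richest"),
    rep(total_population / 5, 5)
  )
}

#' @rdname subgroup_scheme
#' @param urban_share Proportion of the population living in urban areas.
#' @export
residence_scheme <- function(total_population = 17.5e6, urban_share = 0.15) {
  subgroup_scheme(
    "residence",
    c("rural", "urban"),
    total_population * c(1 - urban_share, urban_share)
  )
}

scheme_labels <- function(scheme) as.character(scheme$subgroup)

scheme_dimension <- function(scheme) attr(scheme, "dimension")

n_subgroups <- function(scheme) nrow(scheme)

check_scheme <- function(scheme) {
  if (!inherits(scheme, "subgroup_scheme")) {
    abort("`scheme` must be created with `subgroup_scheme()`.")
  }
  invisible(scheme)
}

# Match a per-subgroup numeric vector against a scheme; names are checked when
# present, length always.
check_subgroup_vector <- function(x, scheme, name = "values") {
  check_scheme(scheme)
  if (length(x) != n_subgroups(scheme)) {
    abort(sprintf("`%s` must have one value per subgroup (%d expected, got %d).",
                  name, n_subgroups(scheme), length(x)))
  }
  if (!is.null(names(x)) && !identical(names(x), scheme_labels(scheme))) {
    abort(sprintf("`%s` names must match the scheme's subgroup labels in order.", name))
  }
  invisible(x)
}
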