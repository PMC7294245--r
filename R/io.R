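#' Read an intervention catalog table
#'
#' The catalog lists, per candidate intervention: the eligible population per
#' year (persons), the incremental cost per use (USD), the incremental health
#' benefit per use (DALYs averted), and whether the intervention is part of
#' the current health benefits package.
#'
#' @param path Path to a CSV file with header columns `name`,
#'   `eligible_population`, `incremental_cost`, `incremental_benefit`,
#'   `in_ehp` (0/1 or true/false).
#'
#' @return A tibble with one row per intervention; `in_ehp` is logical.
#' @export
read_intervention_table <- function(path) {
  raw <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE)
  needed <- c("name", "eligible_population", "incremental_cost",
              "incremental_benefit", "in_ehp")
  missing_cols <- setdiff(needed, names(raw))
  if (length(missing_cols) > 0L) {
    abort(sprintf("catalog is missing column(s): %s.",
                  paste(missing_cols, collapse = ", ")))
  }
  parse_num <- function(col) {
    x <- suppressWarnings(as.numeric(raw[[col]]))
    bad <- which(is.na(x) & !is.na(raw[[col]]) & raw[[col]] != "")
    if (length(bad) > 0L) {
      abort(sprintf("non-numeric value in column '%s' at data row %d ('%s').",
                    col, bad[1], raw[[col]][bad[1]]))
    }
    x
  }
  in_ehp_raw <- tolower(trimws(raw$in_ehp))
  if (!all(in_ehp_raw %in% c("0", "1", "true", "false"))) {
    abort("`in_ehp` must contain only 0/1/true/false.")
  }
  out <- tibble::tibble(
    name = raw$name,
    eligible_population = parse_num("eligible_population"),
    incremental_cost = parse_num("incremental_cost"),
    incremental_benefit = parse_num("incremental_benefit"),
    in_ehp = in_ehp_raw %in% c("1", "true")
  )
  if (any(out$eligible_population < 0, na.rm = TRUE)) {
    abort("`eligible_population` must be nonnegative.")
  }
  if (any(out$incremental_cost < 0, na.rm = TRUE)) {
    abort("`incremental_cost` must be nonnegative.")
  }
  out
}

#' Read a per-intervention share table
#'
#' Wide CSV with one row per intervention and one column per subgroup label.
#' Blank cells are preserved as missing (`NA`) so that downstream imputation
#' can distinguish "not observed" from zero. If every subgroup column header
#' ends in `%`, or `percent = TRUE`, values are divided by 100 at read time.
#'
#' @param path CSV path. First column must be `intervention` (or `name`);
#'   remaining columns must match the scheme's subgroup labels in order.
#' @param scheme A [subgroup_scheme()].
#' @param kind Share kind; see [validate_share_vector()].
#' @param percent Interpret cells as percentages. Defaults to auto-detection
#'   from a `%` suffix on the subgroup column headers.
#'
#' @return A long tibble with columns `intervention`, `subgroup`, `value`,
#'   `kind`, `imputed` (all `FALSE` on read).
#' @export
read_share_table <- function(path, scheme, kind, percent = NULL) {
  check_scheme(scheme)
  kind <- match.arg(kind, share_kinds)
  raw <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE)
  id_col <- intersect(c("intervention", "name"), names(raw))[1]
  if (is.na(id_col)) {
    abort("share table must have an 'intervention' (or 'name') column.")
  }
  value_cols <- setdiff(names(raw), id_col)
  stripped <- sub("%$", "", value_cols)
  if (is.null(percent)) percent <- all(grepl("%$", value_cols))
  if (!identical(stripped, scheme_labels(scheme))) {
    abort(sprintf("share table columns (%s) do not match scheme subgroups (%s).",
                  paste(stripped, collapse = ", "),
                  paste(scheme_labels(scheme), collapse = ", ")))
  }
  vals <- sapply(value_cols, function(col) {
    x <- suppressWarnings(as.numeric(raw[[col]]))
    bad <- which(is.na(x) & !is.na(raw[[col]]) & raw[[col]] != "")
    if (length(bad) > 0L) {
      abort(sprintf("non-numeric cell in column '%s' at data row %d.", col, bad[1]))
    }
    x
  })
  vals <- matrix(vals, nrow = nrow(raw))
  if (percent) vals <- vals / 100
  for (i in seq_len(nrow(vals))) {
    validate_share_vector(vals[i, ], scheme, kind)
  }
  new_share_table(raw[[id_col]], vals, scheme, kind)
}

#' Write a results table to CSV
#'
#' Writes any of the pipeline's tabular results (distributional impact tables,
#' equity-plane points, HALE distributions, scenario grids) as an RFC-4180
#' CSV that round-trips numeric values exactly enough to be re-read to within
#' 1e-9.
#'
#' @param results A data frame of results.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_results_table <- function(results, path) {
  if (!is.data.frame(results)) {
    abort("`results` must be a data frame.")
  }
  out <- as.data.frame(results)
  for (j in seq_along(out)) {
    if (is.factor(out[[j]])) out[[j]] <- as.character(out[[j]])
    if (is.numeric(out[[j]])) out[[j]] <- formatC(out[[j]], digits = 15,
                                                 format = "g")
  }
  readr::write_csv(tibble::as_tibble(out), path, progress = FALSE)
  invisible(path)
}

#' Opportunity-cost model
#'
#' Health opportunity cost converts incremental spending into forgone health:
#' every `dollars_per_daly` USD of incremental cost displaces one DALY averted
#' elsewhere in the system, and the forgone DALYs are distributed over
#' subgroups according to `shares` (the opportunity-cost share vector F,
#' proxied by the socioeconomic distribution of public/church healthcare
#' utilization).
#'
#' @param dollars_per_daly Marginal productivity of health expenditure, USD
#'   per DALY (base case 61).
#' @param shares Named or plain numeric vector of opportunity-cost shares,
#'   one per subgroup, summing to 1.
#' @param scheme A [subgroup_scheme()].
#' @return A list of class `oc_model`.
#' @examples
#' oc_model(61, c(0.23, 0.22, 0.20, 0.19, 0.16), wealth_quintile_scheme())
#' @export
oc_model <- function(dollars_per_daly, shares, scheme) {
  check_scalar_number(dollars_per_daly, "dollars_per_daly")
  if (dollars_per_daly <= 0) abort("`dollars_per_daly` must be positive.")
  shares <- validate_share_vector(shares, scheme, "opportunity_cost_share")
  structure(list(dollars_per_daly = dollars_per_daly, shares = shares,
                 scheme = scheme),
            class = "oc_model")
}

#' Read an analysis configuration from YAML
#'
#' The configuration bundles the inequality-aversion parameter, the
#' opportunity-cost model, the subgroup scheme, the total-cost mode, the
#' scenario list and the random seed for one pipeline run.
#'
#' @param path YAML file with top-level keys `aversion`, `dollars_per_daly`,
#'   `oc_shares`, `scheme` (with `dimension`, `labels`, `populations`),
#'   `cost_mode`, optional `scenarios`, `seed`, `n_households`,
#'   `n_interventions`, `ehp_fraction`.
#' @return A list of class `dcea_config`.
#' @export
read_analysis_config <- function(path) {
  raw <- yaml::read_yaml(path)
  for (key in c("aversion", "dollars_per_daly", "oc_shares", "scheme")) {
    if (is.null(raw[[key]])) {
      abort(sprintf("analysis config is missing required key '%s'.", key))
    }
  }
  scheme <- subgroup_scheme(raw$scheme$dimension,
                            as.character(raw$scheme$labels),
                            as.numeric(raw$scheme$populations))
  dcea_config(
    aversion = raw$aversion,
    oc = oc_model(raw$dollars_per_daly, as.numeric(raw$oc_shares), scheme),
    scheme = scheme,
    cost_mode = raw$cost_mode %||% "per_treated",
    scenarios = raw$scenarios %||% list(),
    seed = raw$seed %||% 1L,
    n_households = raw$n_households %||% 5000L,
    n_interventions = raw$n_interventions %||% 73L,
    ehp_fraction = raw$ehp_fraction %||% 51 / 73
  )
}

#' @rdname read_analysis_config
#' @param aversion Atkinson inequality-aversion parameter (epsilon >= 0; base
#'   case 10).
#' @param oc An [oc_model()].
#' @param scheme A [subgroup_scheme()].
#' @param cost_mode One of `"per_treated"`, `"per_eligible"`, `"fixed"`.
#' @param scenarios List of scenario specifications for [run_scenario_suite()].
#' @param seed Integer random seed.
#' @param n_households,n_interventions,ehp_fraction Synthesis sizes used when
#'   the pipeline generates its own inputs.
#' @export
dcea_config <- function(aversion = 10, oc, scheme,
                        cost_mode = c("per_treated", "per_eligible", "fixed"),
                        scenarios = list(), seed = 1L,
                        n_households = 5000L, n_interventions = 73L,
                        ehp_fraction = 51 / 73) {
  check_scalar_number(aversion, "aversion", min = 0)
  cost_mode <- match.arg(cost_mode)
  check_scheme(scheme)
  if (!inherits(oc, "oc_model")) abort("`oc` must be an `oc_model()`.")
  structure(list(aversion = aversion, oc = oc, scheme = scheme,
                 cost_mode = cost_mode, scenarios = scenarios,
                 seed = as.integer(seed),
                 n_households = as.integer(n_households),
                 n_interventions = as.integer(n_interventions),
                 ehp_fraction = ehp_fraction),
            class = "dcea_config")
}
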