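#' Age band scheme for abridged lifetables
#'
#' The base scheme uses 5-year bands from birth to 55, a single 55-75 band,
#' and excludes deaths above 75; the table is closed at 75.
#'
#' @param breaks Increasing vector of band boundaries starting at 0.
#' @return Tibble with `band_start`, `band_end`, `width` and a `band` label.
#' @examples
#' age_band_scheme()
#' @export
age_band_scheme <- function(breaks = c(seq(0, 55, by = 5), 75)) {
  if (breaks[1] != 0 || any(diff(breaks) <= 0)) {
    abort("`breaks` must start at 0 and be strictly increasing.")
  }
  tibble::tibble(
    band_start = head(breaks, -1),
    band_end = tail(breaks, -1),
    width = diff(breaks),
    band = sprintf("%g-%g", head(breaks, -1), tail(breaks, -1))
  )
}

#' Derive per-subgroup relative mortality factors from death reports
#'
#' Respondent-reported deaths (siblings at all ages, own children at ages
#' 0-35) proxy the socioeconomic pattern of mortality, using the respondent's
#' subgroup as a proxy for that of the deceased. Per age band, the subgroup
#' death rate (reported deaths per responding household) is normalized so the
#' population-weighted mean factor is 1; reference mortality rates are later
#' multiplied by these factors.
#'
#' @param microdata Microdata with wealth quintiles assigned and death
#'   reports present.
#' @param mode `"siblings_and_children"` (base case) or `"children_only"`
#'   (offspring deaths up to age 20 only).
#' @param scheme A [subgroup_scheme()]; its population shares weight the
#'   normalization.
#' @param age_bands An [age_band_scheme()].
#' @return Tibble with columns `subgroup`, `band`, `factor`. Subgroup-bands
#'   with zero exposure or zero overall deaths get factor 1 with a warning.
#' @export
derive_mortality_pattern <- function(microdata,
                                     mode = c("siblings_and_children", "children_only"),
                                     scheme = wealth_quintile_scheme(),
                                     age_bands = age_band_scheme()) {
  mode <- match.arg(mode)
  hh <- microdata$households
  if (is.null(hh$wealth_quintile)) {
    abort("wealth quintiles not assigned; run `compute_wealth_index()` first.")
  }
  d <- microdata$deaths
  if (mode == "children_only") {
    d <- d[d$relation == "child" & d$age_at_death <= 20, , drop = FALSE]
  }
  labs <- scheme_labels(scheme)
  q <- hh$wealth_quintile[match(d$household_id, hh$household_id)]
  d$group <- factor(labs[q], levels = labs)
  d$band <- cut(d$age_at_death, c(age_bands$band_start, max(age_bands$band_end)),
                labels = age_bands$band, right = FALSE, include.lowest = TRUE)
  d <- d[!is.na(d$band), , drop = FALSE]
  exposure <- as.numeric(table(factor(labs[hh$wealth_quintile], levels = labs)))
  counts <- table(d$group, d$band)
  w <- scheme$share
  out <- vector("list", nrow(age_bands))
  zero_bands <- 0L
  for (b in seq_len(nrow(age_bands))) {
    rate <- as.numeric(counts[, age_bands$band[b]]) / exposure
    mean_rate <- sum(w * rate)
    if (mean_rate == 0 || any(exposure == 0)) {
      zero_bands <- zero_bands + 1L
      f <- rep(1, length(labs))
    } else {
      f <- rate / mean_rate
    }
    out[[b]] <- tibble::tibble(subgroup = factor(labs, levels = labs),
                               band = age_bands$band[b], factor = f)
  }
  if (zero_bands > 0L) {
    warn(sprintf("%d age band(s) had no deaths or no exposure; factors set to 1.",
                 zero_bands))
  }
  dplyr::bind_rows(out)
}

#' Build abridged lifetables from reference rates and subgroup factors
#'
#' Subgroup mortality in band x is `reference rate * factor`. Death
#' probabilities follow the standard abridged-lifetable conversion
#' `nqx = n*nMx / (1 + (n - nax)*nMx)` with mid-interval deaths
#' (`nax = n/2`) in every band. Survivorship starts at `l0 = 1`, person-years
#' are trapezoidal (`nLx = n*(lx + lx+n)/2`), and the table is closed at the
#' last band boundary: deaths beyond it are not modelled, so life expectancy
#' is bounded by that age. If `terminal_rate` is supplied the final interval
#' is instead treated as open with `L = l_end / terminal_rate`.
#'
#' @param reference_rates Tibble with columns `band`, `rate` (per
#'   person-year), one row per band of `age_bands`, or a numeric vector.
#' @param factors Tibble `subgroup`/`band`/`factor` as from
#'   [derive_mortality_pattern()], or `NULL` for a single unadjusted table.
#' @param age_bands An [age_band_scheme()].
#' @param terminal_rate Optional mortality rate for an open terminal interval.
#' @return Tibble with one row per subgroup and band: `nMx`, `nqx`, `lx`,
#'   `nLx`, plus per-subgroup life expectancy at birth `ex0` (repeated).
#' @export
build_lifetable <- function(reference_rates, factors = NULL,
                            age_bands = age_band_scheme(),
                            terminal_rate = NULL) {
  rates <- if (is.data.frame(reference_rates)) {
    reference_rates$rate[match(age_bands$band, reference_rates$band)]
  } else {
    as.numeric(reference_rates)
  }
  if (length(rates) != nrow(age_bands) || anyNA(rates) || any(rates <= 0)) {
    abort("need one positive reference rate per age band.")
  }
  if (is.null(factors)) {
    factors <- tidyr::expand_grid(subgroup = factor("all"),
                                  band = age_bands$band)
    factors$factor <- 1
  }
  subgroups <- levels(factor(factors$subgroup))
  out <- purrr::map(subgroups, function(g) {
    f <- factors$factor[factors$subgroup == g][match(age_bands$band,
                                                    factors$band[factors$subgroup == g])]
    m <- rates * f
    n <- age_bands$width
    q <- n * m / (1 + (n - n / 2) * m)
    q <- pmin(q, 1)
    l <- cumprod(c(1, 1 - q))
    lx <- head(l, -1)
    lend <- tail(l, -1)
    L <- n * (lx + lend) / 2
    e0 <- sum(L) +
      if (!is.null(terminal_rate)) l[length(l)] / terminal_rate else 0
    tibble::tibble(subgroup = g, band = age_bands$band, nMx = m, nqx = q,
                   lx = lx, nLx = L, ex0 = e0)
  })
  out <- dplyr::bind_rows(out)
  out$subgroup <- factor(out$subgroup, levels = subgroups)
  out
}

#' Distribute a total YLD burden over subgroups
#'
#' The population YLD rate per band is split so that subgroup g's rate is
#' `total rate * share_g / population_share_g`; the population-weighted mean
#' of the subgroup rates then reproduces the total rate in every band.
#'
#' @param total_yld_by_band Tibble with `band`, `yld_rate` (proportion of
#'   band person-years lived in disability-equivalent states), or a numeric
#'   vector per band.
#' @param disease_shares Per-subgroup shares of the disease burden proxying
#'   the YLD distribution (sums to 1).
#' @param scheme A [subgroup_scheme()].
#' @param age_bands An [age_band_scheme()].
#' @return Tibble `subgroup` x `band` with column `yld_rate`.
#' @export
distribute_yld <- function(total_yld_by_band, disease_shares, scheme,
                           age_bands = age_band_scheme()) {
  rates <- if (is.data.frame(total_yld_by_band)) {
    total_yld_by_band$yld_rate[match(age_bands$band, total_yld_by_band$band)]
  } else {
    as.numeric(total_yld_by_band)
  }
  if (length(rates) != nrow(age_bands) || anyNA(rates)) {
    abort("need one YLD rate per age band.")
  }
  disease_shares <- validate_share_vector(disease_shares, scheme,
                                          "prevalence_share")
  mult <- disease_shares / scheme$share
  tidyr::expand_grid(subgroup = scheme$subgroup, band = age_bands$band) |>
    dplyr::mutate(yld_rate = unname(rates[match(.data$band, age_bands$band)] *
                                      mult[as.integer(.data$subgroup)]))
}

#' Sullivan-method health-adjusted life expectancy
#'
#' Weights each band's person-years by the proportion of time lived free of
#' disability: `HALE = sum(nLx * (1 - yld)) / l0`. Equal to life expectancy
#' iff all YLD rates are zero.
#'
#' @param lifetable Output of [build_lifetable()].
#' @param yld_rates Tibble `subgroup`/`band`/`yld_rate` (values in \[0, 1)),
#'   as from [distribute_yld()], or a numeric vector recycled per band for
#'   all subgroups.
#' @param scheme Optional [subgroup_scheme()]; when given, the result carries
#'   population weights and is a `dcea_hale` distribution.
#' @return Tibble with one row per subgroup: `hale`, `le`, and (with a
#'   scheme) `population` and `weight`.
#' @examples
#' lt <- build_lifetable(rep(0.01, 12))
#' sullivan_hale(lt, rep(0.1, 12))
#' @export
sullivan_hale <- function(lifetable, yld_rates, scheme = NULL) {
  bands <- unique(lifetable$band)
  if (is.numeric(yld_rates)) {
    yld_rates <- tidyr::expand_grid(subgroup = unique(lifetable$subgroup),
                                    band = bands) |>
      dplyr::mutate(yld_rate = rep(as.numeric(yld_rates),
                                   length(unique(lifetable$subgroup))))
  }
  if (any(yld_rates$yld_rate < 0 | yld_rates$yld_rate >= 1)) {
    abort("YLD rates must lie in [0, 1).")
  }
  joined <- dplyr::left_join(lifetable,
                             yld_rates[c("subgroup", "band", "yld_rate")],
                             by = c("subgroup", "band"))
  if (anyNA(joined$yld_rate)) abort("missing YLD rate for some subgroup-band.")
  out <- dplyr::summarise(
    dplyr::group_by(joined, .data$subgroup),
    hale = sum(.data$nLx * (1 - .data$yld_rate)),
    le = .data$ex0[1],
    .groups = "drop"
  )
  if (!is.null(scheme)) {
    check_scheme(scheme)
    out <- out[match(scheme_labels(scheme), as.character(out$subgroup)), ]
    out$population <- scheme$population
    out$weight <- scheme$share
    class(out) <- c("dcea_hale", class(out))
  }
  out
}

#' Packaged synthetic reference rates
#'
#' Stylized single-country reference tables standing in for published
#' all-cause mortality and YLD rates by age band. They are synthetic: chosen
#' so the truncated-at-75 life expectancy (about 59.3 years) and mean HALE
#' (about 52.7 healthy years) sit in the range reported for a low-income
#' high-burden setting. Shipped as plain CSV under `inst/extdata/`.
#'
#' @return A tibble keyed by `band` with `rate` (mortality) or `yld_rate`.
#' @export
default_reference_mortality <- function() {
  readr::read_csv(system.file("extdata", "synthetic_reference_mortality.csv",
                              package = "dcea"),
                  col_types = "cddd", progress = FALSE)
}

#' @rdname default_reference_mortality
#' @export
default_reference_yld <- function() {
  readr::read_csv(system.file("extdata", "synthetic_reference_yld.csv",
                              package = "dcea"),
                  col_types = "cd", progress = FALSE)
}

#' Baseline HALE distribution from microdata
#'
#' Convenience wrapper for Stage 2: derives the mortality pattern from death
#' reports, builds per-subgroup lifetables on the reference rates, proxies
#' the YLD distribution with the survey disease distribution, and returns the
#' per-subgroup HALE distribution with population weights.
#'
#' @param microdata Complete microdata with wealth quintiles assigned.
#' @param scheme A [subgroup_scheme()].
#' @param mode Mortality-pattern source mode, see [derive_mortality_pattern()].
#' @param yld_shares Optional per-subgroup disease shares for the YLD split;
#'   defaults to the pooled prevalence distribution observed in the survey.
#' @return A `dcea_hale` tibble.
#' @export
baseline_hale <- function(microdata, scheme = wealth_quintile_scheme(),
                          mode = "siblings_and_children", yld_shares = NULL) {
  pattern <- derive_mortality_pattern(microdata, mode = mode, scheme = scheme)
  lt <- build_lifetable(default_reference_mortality(), pattern)
  if (is.null(yld_shares)) {
    p <- person_groups(microdata,
                       if (scheme_dimension(scheme) == "wealth") "wealth" else "residence")
    cases <- tapply(!is.na(p$disease), p$group, sum)
    cases[is.na(cases)] <- 0
    yld_shares <- as.numeric(cases) / sum(cases)
  }
  yld <- distribute_yld(default_reference_yld(), yld_shares, scheme)
  sullivan_hale(lt, yld, scheme = scheme)
}
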