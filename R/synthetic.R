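#' Configure the synthetic household-survey generator
#'
#' The generator emulates the structure of the household surveys that feed an
#' aggregate DCEA: households with an asset battery and urban/rural residence,
#' members with two-week-recall disease reports, care seeking and provider
#' codes, and respondent-reported sibling/offspring deaths. Socioeconomic
#' structure is injected through a latent household wealth score in \[0, 1\]:
#' asset ownership, disease prevalence, service uptake and mortality hazards
#' all depend on the household's latent wealth quintile through configurable
#' multiplicative gradient factors.
#'
#' Assets are independent Bernoulli given the latent score with a logistic
#' link: asset `j` has an ownership threshold evenly spaced in \[0, 1\] and a
#' common discrimination (slope). A large battery with high discrimination
#' makes the derived asset index an accurate ranking of latent wealth, which
#' is what the parameter-recovery guarantees of the estimators rely on.
#'
#' @param n_households Number of households to simulate.
#' @param seed Integer seed; all randomness in the generator flows from it.
#' @param urban_fraction Probability a household is urban (base 0.15).
#' @param n_assets Number of binary assets in the battery.
#' @param asset_discrimination Logistic slope linking latent wealth to asset
#'   ownership.
#' @param mean_extra_members Household size is `1 + Poisson(mean_extra_members)`.
#' @param diseases Tibble with columns `disease`, `base_prevalence`,
#'   `base_uptake` and list-columns `prev_gradient`, `uptake_gradient` (five
#'   multiplicative factors each, poorest to richest).
#' @param provider_public Probability (scalar or per-quintile vector) that a
#'   care episode uses a public/church provider.
#' @param mortality_gradient Five multiplicative hazard factors, poorest to
#'   richest.
#' @param sibling_hazard,child_hazard Expected reported deaths per respondent
#'   per age band (siblings: all bands to 75; children: bands to 35).
#' @param age_bands An [age_band_scheme()].
#'
#' @return A list of class `synthetic_config`.
#' @examples
#' cfg <- synthetic_config(n_households = 200, seed = 1)
#' md <- generate_survey(cfg)
#' nrow(md$households)
#' @export
synthetic_config <- function(n_households,
                             seed = 1L,
                             urban_fraction = 0.15,
                             n_assets = 30L,
                             asset_discrimination = 40,
                             mean_extra_members = 3.3,
                             diseases = default_disease_table(),
                             provider_public = 0.85,
                             mortality_gradient = c(1.25, 1.10, 1.00, 0.90, 0.80),
                             sibling_hazard = NULL,
                             child_hazard = NULL,
                             age_bands = age_band_scheme()) {
  if (!is.numeric(n_households) || n_households <= 0) {
    abort("`n_households` must be a positive count.")
  }
  if (urban_fraction < 0 || urban_fraction > 1) {
    abort("`urban_fraction` must be in [0, 1].")
  }
  if (any(mortality_gradient <= 0)) {
    abort("`mortality_gradient` factors must be > 0.")
  }
  for (i in seq_len(nrow(diseases))) {
    if (any(diseases$prev_gradient[[i]] <= 0) ||
        any(diseases$uptake_gradient[[i]] <= 0)) {
      abort("disease gradient factors must all be > 0.")
    }
  }
  nb <- nrow(age_bands)
  if (is.null(sibling_hazard)) {
    # roughly: several siblings observed over decades, rates echoing the
    # packaged reference lifetable shape
    sibling_hazard <- default_reference_mortality()$rate * 5
  }
  if (is.null(child_hazard)) {
    ref <- default_reference_mortality()
    child_hazard <- ifelse(ref$band_start < 35, ref$rate * 3, 0)
  }
  if (any(sibling_hazard < 0) || any(child_hazard < 0)) {
    abort("hazards must be nonnegative.")
  }
  if (length(sibling_hazard) != nb || length(child_hazard) != nb) {
    abort("hazards must have one entry per age band.")
  }
  structure(list(
    n_households = as.integer(n_households), seed = as.integer(seed),
    urban_fraction = urban_fraction, n_assets = as.integer(n_assets),
    asset_discrimination = asset_discrimination,
    mean_extra_members = mean_extra_members, diseases = diseases,
    provider_public = rep(provider_public, length.out = 5),
    mortality_gradient = mortality_gradient,
    sibling_hazard = sibling_hazard, child_hazard = child_hazard,
    age_bands = age_bands
  ), class = "synthetic_config")
}

#' Default disease table for the synthetic survey
#'
#' Three stylized two-week-recall conditions with wealth gradients in
#' prevalence and uptake. The first condition's gradients echo the pattern of
#' survey-reported cases and care seeking in the source setting (cases
#' concentrated in the poorest quintile, uptake highest in the poorest and
#' richer quintiles).
#'
#' @return A tibble usable as the `diseases` field of [synthetic_config()].
#' @export
default_disease_table <- function() {
  tibble::tibble(
    disease = c("diarrhoea", "malaria", "respiratory"),
    base_prevalence = c(0.12, 0.12, 0.10),
    base_uptake = c(0.45, 0.50, 0.40),
    prev_gradient = list(
      c(1.50, 1.20, 1.00, 0.80, 0.60),
      c(1.40, 1.20, 1.00, 0.85, 0.70),
      c(1.20, 1.10, 1.00, 0.95, 0.90)
    ),
    uptake_gradient = list(
      c(1.05, 0.93, 1.00, 1.08, 0.98),
      c(0.90, 0.95, 1.00, 1.05, 1.10),
      c(1.00, 1.00, 1.00, 1.00, 1.00)
    )
  )
}

clip01 <- function(p, what = "probability") {
  if (any(p > 1 + 1e-12)) {
    warn(sprintf("%s > 1 after applying gradient; clipped.", what))
  }
  pmin(pmax(p, 0), 1)
}

latent_quintile <- function(u) pmax(pmin(ceiling(u * 5), 5L), 1L)

#' Generate synthetic households and members
#'
#' Draws `n_households` households with a latent wealth score uniform on
#' \[0, 1\], urban/rural residence, a binary asset battery, and household
#' members with ages. Subsequent generator stages add disease/care-seeking
#' reports and mortality reports.
#'
#' @param config A [synthetic_config()].
#' @return A list of class `dcea_microdata` with tibbles `households`
#'   (including `asset_*` columns) and `persons`; `deaths` is an empty tibble
#'   until [generate_mortality_reports()] runs.
#' @export
generate_households <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  n <- config$n_households
  set.seed(config$seed)
  u <- runif(n)
  residence <- ifelse(runif(n) < config$urban_fraction, "urban", "rural")
  K <- config$n_assets
  thresholds <- (seq_len(K) - 0.5) / K
  p <- plogis(config$asset_discrimination * outer(u, thresholds, "-"))
  assets <- matrix(rbinom(n * K, 1L, p), n, K)
  colnames(assets) <- sprintf("asset_%02d", seq_len(K))
  size <- 1L + rpois(n, config$mean_extra_members)
  households <- tibble::tibble(
    household_id = seq_len(n),
    latent_wealth = u,
    latent_quintile = latent_quintile(u),
    residence = residence,
    size = size
  )
  households <- dplyr::bind_cols(households, tibble::as_tibble(assets))
  persons <- tibble::tibble(
    household_id = rep(households$household_id, households$size),
    person_id = sequence(households$size),
    age = floor(80 * stats::rbeta(sum(size), 1, 2.2))
  )
  structure(list(households = households, persons = persons,
                 deaths = tibble::tibble(household_id = integer(),
                                         relation = character(),
                                         age_at_death = numeric()),
                 config = config),
            class = "dcea_microdata")
}

#' Add two-week disease reports and care seeking
#'
#' Each member reports at most one disease code for the recall window, drawn
#' with quintile-specific prevalence `base_prevalence * prev_gradient[q]`
#' (clipped to \[0, 1\] with a warning). Conditional on disease, care seeking
#' is Bernoulli with quintile-specific uptake, and each care episode carries a
#' provider code (`"public"` for governmental/church providers, `"other"`
#' otherwise).
#'
#' @param microdata Output of [generate_households()].
#' @param config The same [synthetic_config()].
#' @return `microdata` with `disease`, `care_sought`, `provider` columns on
#'   `persons`.
#' @export
generate_disease_and_careseeking <- function(microdata, config) {
  set.seed(config$seed + 1L)
  persons <- microdata$persons
  hh <- microdata$households
  q <- hh$latent_quintile[match(persons$household_id, hh$household_id)]
  nd <- nrow(config$diseases)
  pmat <- sapply(seq_len(nd), function(i) {
    clip01(config$diseases$base_prevalence[i] *
             config$diseases$prev_gradient[[i]][q], "prevalence")
  })
  pmat <- matrix(pmat, nrow = nrow(persons))
  rowsum_p <- rowSums(pmat)
  over <- rowsum_p > 1
  if (any(over)) {
    warn("per-member disease probabilities sum to > 1 for some members; rescaled.")
    pmat[over, ] <- pmat[over, ] / rowsum_p[over]
  }
  draw <- runif(nrow(persons))
  cum <- pmat
  if (nd > 1) for (j in 2:nd) cum[, j] <- cum[, j - 1] + pmat[, j]
  idx <- rowSums(draw > cum) + 1L  # nd + 1 means "no disease"
  disease <- ifelse(idx <= nd, config$diseases$disease[pmin(idx, nd)], NA_character_)
  umat <- sapply(seq_len(nd), function(i) {
    clip01(config$diseases$base_uptake[i] *
             config$diseases$uptake_gradient[[i]][q], "uptake")
  })
  umat <- matrix(umat, nrow = nrow(persons))
  u_prob <- ifelse(is.na(disease), 0, umat[cbind(seq_len(nrow(persons)),
                                                 pmin(idx, nd))])
  care <- runif(nrow(persons)) < u_prob
  pub <- config$provider_public[q]
  provider <- ifelse(care, ifelse(runif(nrow(persons)) < pub, "public", "other"),
                     NA_character_)
  persons$disease <- disease
  persons$care_sought <- care
  persons$provider <- provider
  microdata$persons <- persons
  microdata
}

#' Add respondent-reported sibling and offspring deaths
#'
#' One respondent per household reports deaths among siblings (any age up to
#' the last age band) and among their own children (ages 0-35 only). Counts
#' per age band are Poisson with mean `hazard[band] * mortality_gradient[q]`;
#' an age at death is drawn uniformly within the band.
#'
#' @inheritParams generate_disease_and_careseeking
#' @return `microdata` with a populated `deaths` tibble (`household_id`,
#'   `relation` in `"sibling"`/`"child"`, `age_at_death`).
#' @export
generate_mortality_reports <- function(microdata, config) {
  set.seed(config$seed + 2L)
  hh <- microdata$households
  bands <- config$age_bands
  g <- config$mortality_gradient[hh$latent_quintile]
  draw_rel <- function(hazard, relation, max_age = Inf) {
    out <- vector("list", nrow(bands))
    for (b in seq_len(nrow(bands))) {
      if (hazard[b] <= 0 || bands$band_start[b] >= max_age) next
      counts <- rpois(nrow(hh), hazard[b] * g)
      if (sum(counts) == 0L) next
      upper <- min(bands$band_end[b], max_age)
      out[[b]] <- tibble::tibble(
        household_id = rep(hh$household_id, counts),
        relation = relation,
        age_at_death = runif(sum(counts), bands$band_start[b], upper)
      )
    }
    dplyr::bind_rows(out)
  }
  deaths <- dplyr::bind_rows(
    draw_rel(config$sibling_hazard, "sibling"),
    draw_rel(config$child_hazard, "child", max_age = 35)
  )
  microdata$deaths <- deaths
  microdata
}

#' Run all generator stages
#'
#' @param config A [synthetic_config()].
#' @return A complete `dcea_microdata` list.
#' @export
generate_survey <- function(config) {
  md <- generate_households(config)
  md <- generate_disease_and_careseeking(md, config)
  generate_mortality_reports(md, config)
}

#' Generate a synthetic intervention catalog with share tables
#'
#' Emulates a cost-effectiveness evidence base: `m` interventions with
#' eligible populations, unit costs in \[0.1, 500\] USD, unit benefits in
#' \[0.001, 5\] DALYs, an EHP-membership flag on a configurable fraction, and
#' matching prevalence-share and uptake tables whose wealth gradients are
#' noisy versions of configurable base patterns. A fraction of share rows can
#' be left missing to exercise the imputation rules.
#'
#' @param m Number of interventions.
#' @param seed Integer seed.
#' @param scheme A [subgroup_scheme()] (five wealth quintiles).
#' @param ehp_fraction Fraction of interventions flagged as in the current
#'   package.
#' @param prevalence_pattern,uptake_pattern Base per-quintile patterns around
#'   which intervention-level shares are drawn.
#' @param missing_fraction Fraction of interventions whose share rows are
#'   blanked (missing), exercising imputation.
#' @return A list with `catalog` (tibble as from [read_intervention_table()]),
#'   `prevalence` and `uptake` (long share tibbles).
#' @export
generate_intervention_catalog <- function(m, seed = 1L,
                                          scheme = wealth_quintile_scheme(),
                                          ehp_fraction = 51 / 73,
                                          prevalence_pattern = c(0.36, 0.16, 0.23, 0.13, 0.12),
                                          uptake_pattern = c(0.48, 0.37, 0.45, 0.49, 0.44),
                                          missing_fraction = 0) {
  if (m < 1) abort("`m` must be >= 1.")
  check_scheme(scheme)
  set.seed(seed + 3L)
  name <- sprintf("intervention_%03d", seq_len(m))
  # unit costs span [0.1, 500] USD; benefits follow from a cost-effectiveness
  # ratio drawn log-uniformly around the $61/DALY opportunity-cost threshold,
  # so the catalog mixes net-beneficial and net-harmful candidates the way a
  # cost-effectiveness evidence base does; benefits clamped to [0.001, 5]
  cost <- exp(runif(m, log(0.1), log(500)))
  icer <- exp(runif(m, log(10), log(200)))
  catalog <- tibble::tibble(
    name = name,
    eligible_population = round(exp(runif(m, log(2e4), log(2e6)))),
    incremental_cost = cost,
    incremental_benefit = pmin(pmax(cost / icer, 0.001), 5),
    in_ehp = seq_len(m) %in% sample(m, round(m * ehp_fraction))
  )
  G <- n_subgroups(scheme)
  prev <- matrix(NA_real_, m, G)
  upt <- matrix(NA_real_, m, G)
  n_missing <- floor(m * missing_fraction)
  missing_rows <- if (n_missing > 0) sample(m, n_missing) else integer()
  for (i in seq_len(m)) {
    if (i %in% missing_rows) next
    d <- prevalence_pattern * exp(stats::rnorm(G, 0, 0.30))
    prev[i, ] <- d / sum(d)
    upt[i, ] <- pmin(uptake_pattern * exp(stats::rnorm(G, 0, 0.15)), 1)
  }
  list(
    catalog = catalog,
    prevalence = new_share_table(name, prev, scheme, "prevalence_share"),
    uptake = new_share_table(name, upt, scheme, "uptake_rate")
  )
}

#' Ground-truth distributional parameters implied by a generator config
#'
#' Returns the prevalence shares (D), uptake rates (E), opportunity-cost
#' shares (F) and normalized mortality factors that the generator's own
#' parameters imply for the five latent wealth quintiles, against which the
#' survey estimators can be checked.
#'
#' @param config A [synthetic_config()].
#' @return A list with per-disease `prevalence_shares` and `uptake` (named
#'   lists of length-5 vectors), `oc_shares`, and `mortality_factors`.
#' @export
synthetic_targets <- function(config) {
  nd <- nrow(config$diseases)
  prev <- lapply(seq_len(nd), function(i) {
    p <- clip01(config$diseases$base_prevalence[i] *
                  config$diseases$prev_gradient[[i]])
    p / sum(p)  # equal quintile population shares by construction
  })
  upt <- lapply(seq_len(nd), function(i) {
    clip01(config$diseases$base_uptake[i] * config$diseases$uptake_gradient[[i]])
  })
  names(prev) <- names(upt) <- config$diseases$disease
  episodes <- rowSums(sapply(seq_len(nd), function(i) {
    clip01(config$diseases$base_prevalence[i] * config$diseases$prev_gradient[[i]]) *
      clip01(config$diseases$base_uptake[i] * config$diseases$uptake_gradient[[i]])
  })) * config$provider_public
  mg <- config$mortality_gradient
  list(prevalence_shares = prev, uptake = upt,
       oc_shares = episodes / sum(episodes),
       mortality_factors = mg / mean(mg))
}

#' Write synthetic microdata to plain-text CSVs
#'
#' @param microdata A `dcea_microdata` list.
#' @param dir Output directory (created if needed). Writes `households.csv`,
#'   `persons.csv`, `deaths.csv`.
#' @return `dir`, invisibly.
#' @export
write_microdata <- function(microdata, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  readr::write_csv(microdata$households, file.path(dir, "households.csv"),
                   progress = FALSE)
  readr::write_csv(microdata$persons, file.path(dir, "persons.csv"),
                   progress = FALSE)
  readr::write_csv(microdata$deaths, file.path(dir, "deaths.csv"),
                   progress = FALSE)
  invisible(dir)
}
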