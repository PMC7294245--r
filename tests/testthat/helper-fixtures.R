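# Shared in-code fixtures: tiny microdata with known quintiles, catalog CSVs.

quintile_labels <- c("poorest", "poorer", "middle", "richer", "richest")

# One household per wealth quintile with a fixed number of disease cases and
# care seekers; all providers public unless stated. Quintiles pre-assigned so
# estimator tests are independent of the wealth-index step.
make_quintile_microdata <- function(cases = c(36, 16, 23, 13, 12),
                                    seekers = round(cases * 0.5),
                                    healthy = 50,
                                    provider = "public") {
  households <- tibble::tibble(
    household_id = 1:5,
    residence = c("rural", "rural", "rural", "urban", "urban"),
    size = cases + healthy,
    wealth_quintile = 1:5
  )
  persons <- purrr::map_dfr(1:5, function(q) {
    n <- cases[q] + healthy
    tibble::tibble(
      household_id = q,
      person_id = seq_len(n),
      age = 30,
      disease = c(rep("rotavirus", cases[q]), rep(NA_character_, healthy)),
      care_sought = c(rep(TRUE, seekers[q]),
                      rep(FALSE, cases[q] - seekers[q]),
                      rep(FALSE, healthy)),
      provider = ifelse(c(rep(TRUE, seekers[q]),
                          rep(FALSE, cases[q] - seekers[q] + healthy)),
                        provider, NA_character_)
    )
  })
  structure(list(households = households, persons = persons,
                 deaths = tibble::tibble(household_id = integer(),
                                         relation = character(),
                                         age_at_death = numeric())),
            class = "dcea_microdata")
}

box1_scheme <- function() wealth_quintile_scheme()

box1_oc <- function() {
  oc_model(61, c(0.23, 0.22, 0.20, 0.19, 0.16), box1_scheme())
}

# Random Dirichlet-ish share vector.
rand_shares <- function(n = 5) {
  x <- stats::rexp(n)
  x / sum(x)
}

write_catalog_csv <- function(rows, path = tempfile(fileext = ".csv")) {
  writeLines(c("name,eligible_population,incremental_cost,incremental_benefit,in_ehp",
               rows), path)
  path
}

small_synth_config <- function(n = 500, seed = 1L, ...) {
  synthetic_config(n_households = n, seed = seed, ...)
}

# Long share tibble for one intervention (test-side constructor).
new_share_table_for_test <- function(name, values, scheme,
                                     kind = "prevalence_share") {
  tibble::tibble(
    intervention = name,
    subgroup = factor(quintile_labels, levels = quintile_labels),
    value = as.numeric(values),
    kind = kind,
    imputed = FALSE
  )
}
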