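# Shared fixtures: tiny configurations and a hand-built panel.

# Flat operating point from the published cohort-1 diabetic mobility rates.
TABLE_POINT <- c(onset = 0.067, recover = 0.159, die_nd = 0.029, die_dis = 0.045)

zero_hazard_config <- function(n = 50, seed = 1) {
  synthetic_config(
    n, cohort = 1, seed = seed,
    true_curves = constant_curves(0, 0, 0, 0),
    diabetes_prevalence = 0, diabetes_annual_incidence = 0,
    baseline_disability_prevalence = c(diabetes = 0, no_diabetes = 0)
  )
}

flat_config <- function(n, seed = 1, p = TABLE_POINT, ...) {
  synthetic_config(
    n, cohort = 1, seed = seed,
    true_curves = constant_curves(p[["onset"]], p[["recover"]],
                                  p[["die_nd"]], p[["die_dis"]]),
    diabetes_prevalence = 0, diabetes_annual_incidence = 0,
    baseline_disability_prevalence = c(diabetes = 0, no_diabetes = 0),
    ...
  )
}

reference_lifetable <- function(sex) {
  path <- system.file("extdata",
                      sprintf("reference_lifetable_%s.csv", sex),
                      package = "disablife")
  out <- utils::read.csv(path)
  out$sex <- sex
  out
}

# Build a minimal well-formed panel from a compact wave-by-wave description.
# `status` per wave: "N" (non-disabled), "D" (disabled in every domain),
# "M" (alive, nonresponse), "X" (dead). Items are set so classification
# reproduces the status exactly.
toy_panel <- function(person_statuses, baseline_year = 1992,
                      birth_year = 1936, sex = "female") {
  rows <- list()
  n <- length(person_statuses)
  birth_year <- rep_len(birth_year, n)
  sex <- rep_len(sex, n)
  for (pid in seq_len(n)) {
    st <- person_statuses[[pid]]
    death_year <- NA_real_
    for (w in seq_along(st)) {
      yr <- baseline_year + 2 * (w - 1)
      code <- st[[w]]
      alive <- code != "X"
      if (!alive && is.na(death_year)) death_year <- yr - 1
      responded <- if (!alive) NA else code != "M"
      disabled <- identical(code, "D")
      item <- function(k) {
        if (!alive || !isTRUE(responded)) rep(NA, 5)
        else if (disabled) rep(TRUE, 5) else rep(FALSE, 5)
      }
      vals <- c(item(1), item(2), item(3))
      names(vals) <- c(paste0("mob", 1:5), paste0("iadl", 1:5), paste0("adl", 1:5))
      rows[[length(rows) + 1L]] <- data.frame(
        person_id = pid, wave = w - 1L, interview_year = yr,
        birth_year = birth_year[pid], age = yr - birth_year[pid],
        sex = sex[pid], alive = alive, death_year = death_year,
        diabetes = FALSE, responded = responded, sample_weight = 1,
        t(vals)
      )
    }
  }
  out <- data.table::rbindlist(rows)
  data.table::setattr(out, "class", c("disability_panel", class(out)))
  out[]
}
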