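#' Classify disability status in one domain from item responses
#'
#' Threshold rule on the five difficulty flags of a domain: mobility loss is
#' difficulty with at least 4 of the 5 mobility tasks; IADL and ADL
#' disability are difficulty with at least 1 of the 5 tasks. A wave with any
#' missing item in a domain yields a missing status for that wave (the
#' record is excluded from transition fitting but still counts in the IPW
#' denominator).
#'
#' @param items logical matrix (or vector for a single observation) with 5
#'   columns of difficulty flags.
#' @param domain `"mobility"`, `"iadl"` or `"adl"`.
#' @return data.frame with `n_difficulties` (NA if any item missing) and
#'   `disabled` (logical, NA if status missing).
#' @export
classify_domain <- function(items, domain) {
  domain <- match.arg(domain, DOMAINS)
  if (is.null(dim(items))) items <- matrix(items, nrow = 1)
  if (ncol(items) != 5) stopf("exactly 5 item flags required, got %d", ncol(items))
  n_diff <- rowSums(items)  # NA when any item is missing
  thr <- DOMAIN_THRESHOLDS[[domain]]
  data.frame(domain = domain, n_difficulties = n_diff, disabled = n_diff >= thr)
}

#' Assign the fixed diabetes group of each person
#'
#' A person belongs to the diabetes group if a diagnosis is self-reported at
#' the first interview or at any point during the study period; once
#' assigned, the group is fixed for the person's whole record (the analysis
#' contrasts two fixed populations, not a time-varying covariate).
#'
#' @param panel a `disability_panel` (or any data.frame with `person_id` and
#'   logical `diabetes` per wave).
#' @return data.frame with `person_id` and `diabetes_group`
#'   (`"diabetes"` / `"no_diabetes"`).
#' @export
assign_diabetes_group <- function(panel) {
  d <- data.table::as.data.table(panel)
  out <- d[, .(diabetes_group = if (any(diabetes, na.rm = TRUE)) "diabetes"
               else "no_diabetes"), by = person_id]
  as.data.frame(out)
}

#' Assign birth-cohort membership
#'
#' Cohort 1: born 1931-1941 with a 1992 baseline; cohort 2: born 1942-1947
#' with a 2002 baseline. Any other combination is excluded (`NA`).
#'
#' @param birth_year integer vector.
#' @param baseline_year integer vector (recycled).
#' @return integer vector: 1, 2, or `NA` (excluded).
#' @export
assign_cohort <- function(birth_year, baseline_year) {
  n <- max(length(birth_year), length(baseline_year))
  birth_year <- rep_len(birth_year, n)
  baseline_year <- rep_len(baseline_year, n)
  out <- rep(NA_integer_, n)
  out[birth_year >= 1931 & birth_year <= 1941 & baseline_year == 1992] <- 1L
  out[birth_year >= 1942 & birth_year <= 1947 & baseline_year == 2002] <- 2L
  out
}

# Per-wave domain status for every person-wave of a panel (long over domains).
panel_domain_status <- function(panel) {
  d <- data.table::as.data.table(panel)
  pieces <- lapply(DOMAINS, function(dom) {
    cols <- paste0(switch(dom, mobility = "mob", iadl = "iadl", adl = "adl"), 1:5)
    st <- classify_domain(as.matrix(d[, cols, with = FALSE]), dom)
    data.table::data.table(
      person_id = d$person_id, wave = d$wave, domain = dom,
      disabled = st$disabled, n_difficulties = st$n_difficulties
    )
  })
  data.table::rbindlist(pieces)
}

#' Expand a classified panel into discrete-time person-periods
#'
#' One row per person x consecutive-wave interval x domain, carrying the
#' start state (non-disabled / disabled), the end state (non-disabled /
#' disabled / dead, or `NA` when the end wave was not responded to), the
#' interval length in years, age at interval start, sex, cohort, diabetes
#' group and sampling weight. Deaths between waves are always recorded
#' (vital status is known for everyone), so death intervals do not require
#' end-wave response. Persons disabled in a domain at baseline are flagged
#' `baseline_prevalent` for that domain and are excluded from transition
#' estimation ([fit_transition_models()]).
#'
#' @param panel a `disability_panel`.
#' @param domains subset of `c("mobility", "iadl", "adl")`.
#' @return data.frame of person-periods (class `person_periods`).
#' @export
build_person_periods <- function(panel, domains = DOMAINS) {
  d <- data.table::as.data.table(panel)
  data.table::setorder(d, person_id, wave)

  # validation: monotone death, no resurrection, contiguous biennial ages
  chk <- d[, .(bad_res = any(diff(as.integer(alive)) > 0),
               bad_age = any(diff(age) != diff(wave) * 2L)), by = person_id]
  if (any(chk$bad_res)) {
    stopf("resurrection (alive after dead) for person(s) %s",
          paste(head(chk$person_id[chk$bad_res], 5), collapse = ", "))
  }
  if (any(chk$bad_age)) {
    stopf("non-contiguous ages for person(s) %s",
          paste(head(chk$person_id[chk$bad_age], 5), collapse = ", "))
  }

  groups <- assign_diabetes_group(d)
  status <- panel_domain_status(d)

  base <- d[, .(person_id, wave, interview_year, birth_year, age, sex, alive,
                death_year, responded, sample_weight)]
  cohorts <- base[wave == 0, .(person_id,
                               cohort = assign_cohort(birth_year, interview_year))]

  out <- list()
  for (dom in domains) {
    st <- status[domain == dom, .(person_id, wave, disabled)]
    x <- merge(base, st, by = c("person_id", "wave"), sort = FALSE)
    data.table::setorder(x, person_id, wave)
    x[, `:=`(
      end_wave = data.table::shift(wave, type = "lead"),
      end_year = data.table::shift(interview_year, type = "lead"),
      end_alive = data.table::shift(alive, type = "lead"),
      end_responded = data.table::shift(responded, type = "lead"),
      end_disabled = data.table::shift(disabled, type = "lead")
    ), by = person_id]
    prev <- x[wave == 0, .(baseline_prevalent = isTRUE(disabled[1])),
              by = person_id]
    x <- x[!is.na(end_wave)]
    # interval must start at an observed state while alive
    x <- x[alive == TRUE & responded == TRUE & !is.na(disabled)]
    x[, start_state := ifelse(disabled, "dis", "nondis")]
    x[, k := 2L]
    x[, end_state := data.table::fifelse(
      end_alive == FALSE, "dead",
      data.table::fifelse(is.na(end_responded) | end_responded == FALSE |
                            is.na(end_disabled), NA_character_,
                          data.table::fifelse(end_disabled, "dis", "nondis")))]
    x[, domain := dom]
    x <- merge(x, prev, by = "person_id", sort = FALSE)
    out[[dom]] <- x[, .(person_id, domain, wave, end_wave, age, k,
                        start_state, end_state, sex, sample_weight,
                        baseline_prevalent,
                        end_responded = !is.na(end_responded) & end_responded)]
  }
  pp <- data.table::rbindlist(out)
  pp <- merge(pp, groups, by = "person_id", sort = FALSE)
  pp <- merge(pp, cohorts, by = "person_id", sort = FALSE)
  data.table::setorder(pp, domain, person_id, wave)
  data.table::setattr(pp, "class", c("person_periods", class(pp)))
  pp[]
}
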