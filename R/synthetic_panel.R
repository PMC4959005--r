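#' True transition-probability curves for the synthetic panel
#'
#' Annual transition probabilities are logistic in age: for a person of a
#' given sex and diabetes group,
#' \deqn{p(a) = \mathrm{logit}^{-1}(\beta_0 + \beta_1 (a - 50) + \beta_m \cdot male).}
#' One curve per transition (`onset`, `recover`, `die_nd`, `die_dis`) and
#' diabetes group. The defaults are anchored at published annual rates for
#' the 1931-41 birth cohort of U.S. adults (onset of disability around
#' 6-7/100 person-years with diabetes and 2/100 without, remission 16-22/100,
#' mortality rising steeply with age and higher in the disabled state);
#' `cohort = 2` applies logit shifts reproducing the direction and rough size
#' of the published cohort differences (lower incidence, higher remission,
#' slightly lower mortality).
#'
#' @param cohort 1 or 2; selects the operating point.
#' @return A data.frame with columns `diabetes_group`, `transition`,
#'   `intercept` (logit annual probability at age 50, female), `slope`
#'   (logit change per year of age) and `male` (logit offset for men),
#'   usable as the `true_curves` field of [synthetic_config()].
#' @export
default_true_curves <- function(cohort = 1) {
  stopifnot(cohort %in% c(1, 2))
  curves <- rbind(
    data.frame(
      diabetes_group = "diabetes", transition = TRANSITIONS,
      intercept = qlogis(c(0.060, 0.185, 0.012, 0.028)),
      slope = c(0.012, -0.015, 0.070, 0.055),
      male = c(-0.25, 0.10, 0.35, 0.35)
    ),
    data.frame(
      diabetes_group = "no_diabetes", transition = TRANSITIONS,
      intercept = qlogis(c(0.019, 0.210, 0.006, 0.012)),
      slope = c(0.020, -0.010, 0.090, 0.075),
      male = c(-0.25, 0.10, 0.35, 0.35)
    )
  )
  if (cohort == 2) {
    shift <- c(onset = -0.55, recover = 0.45, die_nd = -0.15, die_dis = -0.10)
    curves$intercept <- curves$intercept + shift[curves$transition]
  }
  curves
}

#' Flat (age- and sex-constant) true curves
#'
#' Convenience constructor for configurations whose annual probabilities do
#' not vary with age or sex, e.g. the Table-2-style operating point
#' (onset 0.067, remission 0.159, mortality 0.029 / 0.045).
#'
#' @param onset,recover,die_nd,die_dis annual probabilities in `[0, 1)`.
#' @return A curves data.frame as in [default_true_curves()].
#' @export
constant_curves <- function(onset, recover, die_nd, die_dis) {
  p <- c(onset = onset, recover = recover, die_nd = die_nd, die_dis = die_dis)
  stopifnot(all(p >= 0), all(p < 1))
  do.call(rbind, lapply(c("diabetes", "no_diabetes"), function(g) {
    data.frame(
      diabetes_group = g, transition = TRANSITIONS,
      intercept = qlogis(pmax(p, 1e-12)), slope = 0, male = 0
    )
  }))
}

# Evaluate a true curve: vectorized over persons.
curve_prob <- function(curves, group, transition, age, male) {
  key <- paste(curves$diabetes_group, curves$transition)
  idx <- match(paste(group, transition), key)
  if (anyNA(idx)) stopf("true_curves is missing a (%s, %s) entry",
                        paste(unique(group[is.na(idx)]), collapse = ","), transition)
  eta <- curves$intercept[idx] + curves$slope[idx] * (age - 50) +
    curves$male[idx] * as.numeric(male)
  p <- plogis(eta)
  # a curve whose intercept was set at exactly 0 or 1 on the probability scale
  p[!is.finite(eta) & eta < 0] <- 0
  p[!is.finite(eta) & eta > 0] <- 1
  p
}

#' Default wave-nonresponse (missingness) model
#'
#' Wave-level missing-at-random nonresponse: the log-odds of responding at a
#' follow-up wave (baseline always responds; deaths are always recorded) are
#' linear in age, sex, disability status at the previous wave, and whether
#' the previous wave was responded to. Attrition steepens markedly with age
#' — the design requirement is that complete-case transition estimates be
#' measurably biased while inverse-probability weighting on these same
#' observables removes the bias — and the intercept is calibrated so that
#' per-wave follow-up response stays in the mid-80s percent range reported
#' for the survey the generator emulates (84-91%).
#'
#' @return Named numeric vector of logistic coefficients.
#' @export
default_missingness <- function() {
  c(intercept = 2.12, age = -0.15, male = -0.20,
    lag_disabled = -0.80, lag_response = 1.00)
}

#' Configuration for the synthetic biennial panel generator
#'
#' @param n_persons number of persons.
#' @param cohort 1 (born 1931-1941, baseline 1992) or 2 (born 1942-1947,
#'   baseline 2002).
#' @param n_waves number of biennial waves (default 6, i.e. 10 years of
#'   follow-up).
#' @param true_curves curves data.frame, see [default_true_curves()].
#' @param diabetes_prevalence probability of a diabetes diagnosis at baseline.
#' @param diabetes_annual_incidence annual probability of a new diagnosis
#'   after baseline.
#' @param baseline_disability_prevalence named vector (`diabetes`,
#'   `no_diabetes`): probability of entering the panel already (long-term)
#'   disabled.
#' @param missingness `NULL` for full response, or coefficients as returned by
#'   [default_missingness()].
#' @param weight_sdlog log-SD of the lognormal sampling weights (normalized
#'   to mean 1).
#' @param seed integer RNG seed; identical seeds give byte-identical panels.
#' @return An object of class `synthetic_config`.
#' @export
synthetic_config <- function(n_persons,
                             cohort = 1,
                             n_waves = 6,
                             true_curves = default_true_curves(cohort),
                             diabetes_prevalence = 0.10,
                             diabetes_annual_incidence = 0.01,
                             baseline_disability_prevalence =
                               c(diabetes = 0.22, no_diabetes = 0.08),
                             missingness = NULL,
                             weight_sdlog = 0.5,
                             seed = 1L) {
  stopifnot(n_persons >= 1, cohort %in% c(1, 2), n_waves >= 2)
  cfg <- list(
    n_persons = as.integer(n_persons),
    cohort = as.integer(cohort),
    birth_year_range = if (cohort == 1) c(1931L, 1941L) else c(1942L, 1947L),
    baseline_year = if (cohort == 1) 1992L else 2002L,
    n_waves = as.integer(n_waves),
    true_curves = true_curves,
    diabetes_prevalence = diabetes_prevalence,
    diabetes_annual_incidence = diabetes_annual_incidence,
    baseline_disability_prevalence = baseline_disability_prevalence,
    missingness = missingness,
    weight_sdlog = weight_sdlog,
    seed = as.integer(seed)
  )
  class(cfg) <- "synthetic_config"
  validate_config(cfg)
  cfg
}

# All probability curves must map into (0,1) over the modeled age span, and
# competing probabilities from a state may not exceed 1.
validate_config <- function(cfg) {
  ba <- cfg$baseline_year - rev(cfg$birth_year_range)
  if (any(ba < 50 | ba > 62)) {
    stopf("baseline ages %d-%d fall outside [50, 62]", ba[1], ba[2])
  }
  ages <- 50:72
  for (g in c("diabetes", "no_diabetes")) {
    for (m in c(0, 1)) {
      ps <- lapply(TRANSITIONS, function(tr) curve_prob(cfg$true_curves, g, tr, ages, m))
      names(ps) <- TRANSITIONS
      for (tr in TRANSITIONS) {
        bad <- which(!is.finite(ps[[tr]]) | ps[[tr]] < 0 | ps[[tr]] > 1)
        if (length(bad)) {
          stopf("curve '%s' (%s, %s) outside [0,1] at age %d",
                tr, g, c("female", "male")[m + 1], ages[bad[1]])
        }
      }
      bad <- which(ps$onset + ps$die_nd > 1)
      if (length(bad)) {
        stopf("onset + die_nd exceeds 1 for (%s, %s) at age %d",
              g, c("female", "male")[m + 1], ages[bad[1]])
      }
      bad <- which(ps$recover + ps$die_dis > 1)
      if (length(bad)) {
        stopf("recover + die_dis exceeds 1 for (%s, %s) at age %d",
              g, c("female", "male")[m + 1], ages[bad[1]])
      }
    }
  }
  bp <- cfg$baseline_disability_prevalence
  stopifnot(all(c("diabetes", "no_diabetes") %in% names(bp)),
            all(bp >= 0 & bp < 1))
  invisible(cfg)
}

# Draw item-difficulty counts conditional on the latent domain state, uniform
# over qualifying 5-bit patterns: mobility disabled <=> >= 4 difficulties,
# IADL/ADL disabled <=> >= 1.
draw_item_counts <- function(n, disabled, threshold) {
  counts <- integer(n)
  ch <- choose(5, 0:5)
  hi <- threshold:5          # qualifying counts when disabled
  lo <- 0:(threshold - 1)    # when not disabled
  n_hi <- sum(disabled)
  if (n_hi) counts[disabled] <- sample(hi, n_hi, TRUE, prob = ch[hi + 1])
  n_lo <- sum(!disabled)
  if (n_lo) counts[!disabled] <- sample(lo, n_lo, TRUE, prob = ch[lo + 1])
  counts
}

items_from_counts <- function(counts) {
  n <- length(counts)
  u <- matrix(runif(n * 5), n, 5)
  rank5(u) <= counts
}

#' Simulate a biennial disability panel with known ground truth
#'
#' Each person evolves annually through the five-state structure (not
#' disabled, short-term disabled, not disabled with history, long-term
#' disabled, dead) according to the configuration's true curves; the panel
#' observes the latent disabled / non-disabled status every two years through
#' item responses (5 mobility, 5 IADL, 5 ADL difficulty flags) whose domain
#' classification reproduces the latent state exactly. All three domains are
#' item-level views of one shared latent process, which keeps the single
#' death time coherent with the state-dependent mortality curves. Deaths are
#' always recorded with their exact year; wave nonresponse (if configured)
#' masks the item responses only.
#'
#' @param config a [synthetic_config()].
#' @param keep_latent attach the latent annual state matrix and related
#'   ground-truth vectors as `attr(panel, "latent")` (used by validation
#'   code that counts true annual events).
#' @param keep_complete attach the full-response version of the same panel
#'   (identical draws, nonresponse mask not applied) as
#'   `attr(panel, "complete")`.
#' @return A `data.table` (class `disability_panel`), one row per
#'   person-wave, with columns `person_id`, `wave`, `interview_year`,
#'   `birth_year`, `age`, `sex`, `alive`, `death_year`, `diabetes`,
#'   `responded`, `sample_weight`, and item flags `mob1..mob5`,
#'   `iadl1..iadl5`, `adl1..adl5` (NA when not responded or dead). The
#'   generating config is attached as `attr(panel, "config")`.
#' @export
simulate_panel <- function(config, keep_latent = FALSE, keep_complete = FALSE) {
  stopifnot(inherits(config, "synthetic_config"))
  validate_config(config)
  set.seed(config$seed)
  n <- config$n_persons
  curves <- config$true_curves

  birth_year <- sample(seq(config$birth_year_range[1], config$birth_year_range[2]),
                       n, replace = TRUE)
  male <- runif(n) < 0.5
  sample_weight <- exp(rnorm(n, 0, config$weight_sdlog))
  sample_weight <- sample_weight / mean(sample_weight)

  n_years <- 2L * (config$n_waves - 1L) + 1L
  years <- config$baseline_year + 0:(n_years - 1L)

  # diabetes diagnosis year; dynamics follow the eventual (study-period) group
  diag_at_base <- runif(n) < config$diabetes_prevalence
  diag_year <- ifelse(diag_at_base, config$baseline_year, NA_real_)
  if (n_years > 1) {
    u_inc <- matrix(runif(n * (n_years - 1L)), n)
    for (j in seq_len(n_years - 1L)) {
      new_dx <- is.na(diag_year) & u_inc[, j] < config$diabetes_annual_incidence
      diag_year[new_dx] <- config$baseline_year + j
    }
  }
  group <- ifelse(!is.na(diag_year), "diabetes", "no_diabetes")

  # latent annual five-state process; 1=ND 2=STD 3=NDH 4=LTD 5=DEAD
  bp <- config$baseline_disability_prevalence[group]
  state <- ifelse(runif(n) < bp, 4L, 1L)
  states <- matrix(NA_integer_, n, n_years)
  states[, 1] <- state
  death_year <- rep(NA_real_, n)

  for (j in seq_len(n_years - 1L)) {
    yr <- years[j]
    age_now <- yr - birth_year
    alive <- state != 5L
    nondis <- alive & state %in% c(1L, 3L)
    dis <- alive & state %in% c(2L, 4L)
    u <- runif(n)
    new_state <- state
    if (any(nondis)) {
      p_on <- curve_prob(curves, group[nondis], "onset", age_now[nondis], male[nondis])
      p_dn <- curve_prob(curves, group[nondis], "die_nd", age_now[nondis], male[nondis])
      un <- u[nondis]
      s <- state[nondis]
      s[un < p_on] <- 2L                       # -> short-term disabled
      s[un >= p_on & un < p_on + p_dn] <- 5L   # -> dead
      new_state[nondis] <- s                   # else ND stays ND, NDH stays NDH
    }
    if (any(dis)) {
      p_re <- curve_prob(curves, group[dis], "recover", age_now[dis], male[dis])
      p_dd <- curve_prob(curves, group[dis], "die_dis", age_now[dis], male[dis])
      ud <- u[dis]
      s <- rep(4L, sum(dis))                   # default: (remain) long-term
      s[ud < p_re] <- 3L                       # -> not disabled, with history
      s[ud >= p_re & ud < p_re + p_dd] <- 5L   # -> dead
      new_state[dis] <- s
    }
    died_now <- alive & new_state == 5L
    death_year[died_now] <- yr + 1
    state <- new_state
    states[, j + 1] <- state
  }

  # assemble person-wave records
  wave_cols <- seq(1L, n_years, by = 2L)
  wave_years <- years[wave_cols]
  n_waves <- config$n_waves

  blocks <- vector("list", n_waves)
  resp_prev <- rep(TRUE, n)
  state_prev_wave <- states[, 1]
  for (w in seq_len(n_waves)) {
    yr <- wave_years[w]
    st <- states[, wave_cols[w]]
    alive_w <- st != 5L
    age_w <- yr - birth_year
    if (w == 1L || is.null(config$missingness)) {
      resp <- rep(TRUE, n)
    } else {
      m <- config$missingness
      lag_dis <- state_prev_wave %in% c(2L, 4L)
      eta <- m[["intercept"]] + m[["age"]] * (age_w - 55) +
        m[["male"]] * male + m[["lag_disabled"]] * lag_dis +
        m[["lag_response"]] * resp_prev
      resp <- runif(n) < plogis(eta)
    }
    resp[!alive_w] <- NA

    dis_w <- st %in% c(2L, 4L)
    # items are drawn for every living person-wave; nonresponse masks them
    mob <- items_from_counts(draw_item_counts(n, dis_w, DOMAIN_THRESHOLDS[["mobility"]]))
    iad <- items_from_counts(draw_item_counts(n, dis_w, DOMAIN_THRESHOLDS[["iadl"]]))
    adl <- items_from_counts(draw_item_counts(n, dis_w, DOMAIN_THRESHOLDS[["adl"]]))
    colnames(mob) <- paste0("mob", 1:5)
    colnames(iad) <- paste0("iadl", 1:5)
    colnames(adl) <- paste0("adl", 1:5)
    items <- cbind(mob, iad, adl)
    items[!alive_w, ] <- NA

    blocks[[w]] <- data.table::data.table(
      person_id = seq_len(n),
      wave = w - 1L,
      interview_year = yr,
      birth_year = birth_year,
      age = age_w,
      sex = ifelse(male, "male", "female"),
      alive = alive_w,
      death_year = death_year,
      diabetes = !is.na(diag_year) & diag_year <= yr,
      responded = resp,
      sample_weight = sample_weight,
      items
    )
    resp_prev <- !is.na(resp) & resp
    state_prev_wave <- st
  }
  panel <- data.table::rbindlist(blocks)
  data.table::setorder(panel, person_id, wave)

  complete <- NULL
  if (keep_complete) {
    complete <- data.table::copy(panel)
    complete[alive == TRUE, responded := TRUE]
  }
  # apply the nonresponse mask to item columns
  item_cols <- c(paste0("mob", 1:5), paste0("iadl", 1:5), paste0("adl", 1:5))
  mask <- !is.na(panel$responded) & !panel$responded
  if (any(mask)) {
    panel[mask, (item_cols) := NA]
  }

  data.table::setattr(panel, "config", config)
  if (keep_latent) {
    data.table::setattr(panel, "latent", list(
      states = states, years = years, death_year = death_year,
      group = group, male = male, birth_year = birth_year
    ))
  }
  if (keep_complete) data.table::setattr(panel, "complete", complete)
  data.table::setattr(panel, "class", c("disability_panel", class(panel)))
  panel[]
}

#' Ground-truth transition probability set of a synthetic configuration
#'
#' Evaluates the configuration's true curves on an integer age grid in the
#' tidy `transition_probability_set` layout used by the Markov engine,
#' bypassing estimation entirely.
#'
#' @param config a [synthetic_config()].
#' @param ages integer ages (default 50:70).
#' @return data.frame with columns `age`, `sex`, `diabetes_group`, `cohort`,
#'   `domain`, `transition`, `p`, `se_logit` (0: these are exact).
#' @export
true_probability_set <- function(config, ages = 50:70) {
  grid <- expand.grid(
    age = ages, sex = SEXES, diabetes_group = c("diabetes", "no_diabetes"),
    domain = DOMAINS, transition = TRANSITIONS,
    KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE
  )
  grid$cohort <- config$cohort
  grid$p <- curve_prob(config$true_curves, grid$diabetes_group, grid$transition,
                       grid$age, grid$sex == "male")
  grid$se_logit <- 0
  class(grid) <- c("transition_probability_set", "data.frame")
  grid
}

#' Life-table summary implied by a configuration's true curves
#'
#' Closure used as the oracle for recovery tests: runs the Markov engine
#' directly on the generating curves, bypassing panel simulation and
#' estimation.
#'
#' @param config a [synthetic_config()].
#' @param sex `"female"` or `"male"`.
#' @param diabetes_group `"diabetes"` or `"no_diabetes"`.
#' @param baseline_age model entry age (50 or 60 in the headline analyses).
#' @param domain disability domain (all domains share the latent dynamics,
#'   so this only labels the output).
#' @param end_age model horizon end (default 70).
#' @return One-row life-table summary data.frame, see [summarize_trajectory()].
#' @export
ground_truth_lifetable <- function(config, sex, diabetes_group, baseline_age,
                                   domain = "mobility", end_age = 70) {
  probs <- true_probability_set(config, ages = baseline_age:end_age)
  spec <- markov_spec(baseline_age, end_age)
  traj <- run_cohort(spec, prob_slice(probs, sex, diabetes_group, domain))
  out <- summarize_trajectory(traj, spec)
  out$sex <- sex
  out$diabetes_group <- diabetes_group
  out$cohort <- config$cohort
  out$domain <- domain
  out
}

#' Write / read a panel as CSV (with a JSON config sidecar)
#'
#' Long format, one row per person-wave, `NA` for masked item responses.
#'
#' @param panel a `disability_panel`.
#' @param path CSV output path.
#' @param config_path optional path for a JSON sidecar with the generating
#'   configuration (requires jsonlite).
#' @return `path`, invisibly.
#' @export
write_panel <- function(panel, path, config_path = NULL) {
  data.table::fwrite(panel, path, na = "NA")
  if (!is.null(config_path)) {
    cfg <- attr(panel, "config")
    if (!requireNamespace("jsonlite", quietly = TRUE)) {
      stopf("jsonlite is required to write the config sidecar")
    }
    jsonlite::write_json(cfg, config_path, auto_unbox = TRUE, digits = NA,
                         force = TRUE, pretty = TRUE)
  }
  invisible(path)
}

#' @rdname write_panel
#' @export
read_panel <- function(path) {
  panel <- data.table::fread(path, na.strings = "NA")
  item_cols <- c(paste0("mob", 1:5), paste0("iadl", 1:5), paste0("adl", 1:5))
  for (cl in c(item_cols, "alive", "responded", "diabetes")) {
    if (cl %in% names(panel)) panel[[cl]] <- as.logical(panel[[cl]])
  }
  data.table::setattr(panel, "class", c("disability_panel", class(panel)))
  panel[]
}
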