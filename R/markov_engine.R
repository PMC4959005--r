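#' Five-state Markov cohort model specification
#'
#' States: `ND` (not disabled, no history), `STD` (short-term disabled,
#' < 1 year), `NDH` (not disabled, previous disability), `LTD` (long-term
#' disabled, > 1 year), `DEAD` (absorbing). Annual cycles from
#' `baseline_age` to `end_age`; all initial mass in `ND`.
#'
#' @param baseline_age model entry age (integer in `[50, 69]`).
#' @param end_age horizon end (default 70).
#' @return An object of class `markov_spec` with fields `baseline_age`,
#'   `end_age`, `horizon` (= `end_age - baseline_age` annual cycles).
#' @export
markov_spec <- function(baseline_age, end_age = 70) {
  stopifnot(baseline_age >= 50, baseline_age < end_age, end_age <= 70)
  structure(list(baseline_age = as.integer(baseline_age),
                 end_age = as.integer(end_age),
                 horizon = as.integer(end_age - baseline_age)),
            class = "markov_spec")
}

#' Annual transition matrix at one age
#'
#' Builds the 5x5 row-stochastic matrix from the four annual probabilities:
#' from a non-disabled state (`ND`/`NDH`) a person becomes short-term
#' disabled with `p["onset"]`, dies with `p["die_nd"]`, else remains; from a
#' disabled state the person reverts to `NDH` with `p["recover"]`, dies with
#' `p["die_dis"]`, else is (or remains) long-term disabled. `STD` occupancy
#' therefore lasts exactly one cycle, and `DEAD` is absorbing.
#'
#' @param p named numeric with entries `onset`, `recover`, `die_nd`,
#'   `die_dis`, each in `[0, 1]` with `onset + die_nd <= 1` and
#'   `recover + die_dis <= 1`.
#' @param age optional age label used in error messages.
#' @return 5x5 matrix with dimnames `ND, STD, NDH, LTD, DEAD`.
#' @export
build_transition_matrix <- function(p, age = NULL) {
  req <- TRANSITIONS
  if (!all(req %in% names(p))) stopf("p must have entries %s", paste(req, collapse = ", "))
  p <- p[req]
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1)) {
    stopf("transition probabilities outside [0,1]%s",
          if (is.null(age)) "" else sprintf(" at age %s", age))
  }
  stay_nd <- 1 - p[["onset"]] - p[["die_nd"]]
  stay_dis <- 1 - p[["recover"]] - p[["die_dis"]]
  if (stay_nd < -1e-9 || stay_dis < -1e-9) {
    stopf("simplex violation (negative remainder)%s",
          if (is.null(age)) "" else sprintf(" at age %s", age))
  }
  stay_nd <- max(stay_nd, 0)
  stay_dis <- max(stay_dis, 0)
  M <- matrix(0, 5, 5, dimnames = list(STATES, STATES))
  M["ND", ] <- c(stay_nd, p[["onset"]], 0, 0, p[["die_nd"]])
  M["STD", ] <- c(0, 0, p[["recover"]], stay_dis, p[["die_dis"]])
  M["NDH", ] <- c(0, p[["onset"]], stay_nd, 0, p[["die_nd"]])
  M["LTD", ] <- c(0, 0, p[["recover"]], stay_dis, p[["die_dis"]])
  M["DEAD", ] <- c(0, 0, 0, 0, 1)
  M
}

#' Extract one stratum's age-indexed probabilities from a tidy set
#'
#' @param probs a `transition_probability_set` data.frame (columns `age`,
#'   `sex`, `diabetes_group`, `domain`, `transition`, `p`, ...).
#' @param sex,diabetes_group,domain stratum selectors; a selector may be
#'   omitted (`NULL`) if `probs` is already unique on it.
#' @return data.frame with one row per age and columns `age`, `onset`,
#'   `recover`, `die_nd`, `die_dis`.
#' @export
prob_slice <- function(probs, sex = NULL, diabetes_group = NULL, domain = NULL) {
  d <- as.data.frame(probs)
  if (!is.null(sex)) d <- d[d$sex == sex, ]
  if (!is.null(diabetes_group)) d <- d[d$diabetes_group == diabetes_group, ]
  if (!is.null(domain)) d <- d[d$domain == domain, ]
  if (!nrow(d)) stopf("no probabilities match the requested stratum")
  for (cl in c("sex", "diabetes_group", "domain", "cohort")) {
    if (cl %in% names(d) && length(unique(d[[cl]])) > 1) {
      stopf("probability set is not unique on '%s'; pass a selector", cl)
    }
  }
  wide <- data.frame(age = sort(unique(d$age)))
  for (tr in TRANSITIONS) {
    sub <- d[d$transition == tr, ]
    wide[[tr]] <- sub$p[match(wide$age, sub$age)]
  }
  if (anyNA(wide)) stopf("probability set has missing transitions for some ages")
  wide
}

#' Run the cohort model
#'
#' Deterministic propagation of the state-occupancy vector: all mass starts
#' in `ND` at `baseline_age` and the age-specific annual matrix is applied
#' for each of the `horizon` cycles.
#'
#' @param spec a [markov_spec()].
#' @param slice age-indexed probabilities as returned by [prob_slice()];
#'   every age in `[baseline_age, end_age)` must be present.
#' @return An occupancy trajectory: `(horizon + 1) x 5` matrix, row `t + 1`
#'   holding the state distribution after `t` cycles (class
#'   `occupancy_trajectory`, with the spec attached).
#' @export
run_cohort <- function(spec, slice) {
  stopifnot(inherits(spec, "markov_spec"))
  ages <- spec$baseline_age:(spec$end_age - 1L)
  miss <- setdiff(ages, slice$age)
  if (length(miss)) stopf("missing probability slice for age(s) %s",
                          paste(miss, collapse = ", "))
  occ <- matrix(0, spec$horizon + 1L, 5, dimnames = list(NULL, STATES))
  occ[1, "ND"] <- 1
  for (t in seq_len(spec$horizon)) {
    a <- ages[t]
    row <- slice[slice$age == a, ]
    M <- build_transition_matrix(
      c(onset = row$onset, recover = row$recover,
        die_nd = row$die_nd, die_dis = row$die_dis), age = a)
    occ[t + 1L, ] <- occ[t, ] %*% M
  }
  structure(occ, spec = spec, class = c("occupancy_trajectory", "matrix", "array"))
}

#' Life-table summary of an occupancy trajectory
#'
#' Person-years for a cycle are credited to the state occupied entering it
#' (cycle-start accounting, no half-cycle correction), which makes the
#' conservation identity DFY + DY + LYL = horizon exact. Disability-free
#' years count both `ND` and `NDH` (recovered) occupancy; the average age of
#' disability onset is defined as `baseline_age + DFY`.
#'
#' @param trajectory an occupancy trajectory from [run_cohort()].
#' @param spec the matching [markov_spec()] (taken from the trajectory
#'   attribute when omitted).
#' @return One-row data.frame with `dfy` (disability-free years), `dy`
#'   (disabled years), `tle` (total life expectancy within the horizon),
#'   `lyl` (life-years lost), `onset_age`, `baseline_age`, `horizon`.
#' @export
summarize_trajectory <- function(trajectory, spec = attr(trajectory, "spec")) {
  stopifnot(inherits(spec, "markov_spec"))
  H <- spec$horizon
  occ <- unclass(trajectory)[seq_len(H), , drop = FALSE]
  dfy <- sum(occ[, c("ND", "NDH")])
  dy <- sum(occ[, c("STD", "LTD")])
  data.frame(
    baseline_age = spec$baseline_age, horizon = H,
    dfy = dfy, dy = dy, tle = dfy + dy, lyl = H - dfy - dy,
    onset_age = spec$baseline_age + dfy
  )
}

#' Life-table summaries for every stratum in a probability set
#'
#' @param probs a tidy `transition_probability_set` covering ages
#'   `[min(baseline_ages), end_age)` for each stratum present.
#' @param baseline_ages model entry ages (default 50 and 60).
#' @param end_age horizon end.
#' @return data.frame keyed by `sex`, `diabetes_group`, `cohort`, `domain`,
#'   `baseline_age` with the life-table summary columns.
#' @export
run_population <- function(probs, baseline_ages = c(50, 60), end_age = 70) {
  d <- as.data.frame(probs)
  strata <- unique(d[, intersect(c("sex", "diabetes_group", "cohort", "domain"),
                                 names(d)), drop = FALSE])
  out <- list()
  for (i in seq_len(nrow(strata))) {
    s <- strata[i, ]
    sub <- d
    for (cl in names(strata)) sub <- sub[sub[[cl]] == s[[cl]], ]
    slice <- prob_slice(sub)
    for (ba in baseline_ages) {
      spec <- markov_spec(ba, end_age)
      res <- summarize_trajectory(run_cohort(spec, slice), spec)
      out[[length(out) + 1L]] <- cbind(s, res, row.names = NULL)
    }
  }
  do.call(rbind, out)
}

#' Microsimulation oracle for the cohort model
#'
#' Simulates `n_walkers` independent individual state paths with the same
#' annual probabilities and averages their occupancy. Used as an independent
#' cross-check of [run_cohort()]: the two agree in expectation, with
#' binomial Monte Carlo error.
#'
#' @inheritParams run_cohort
#' @param n_walkers number of simulated individuals.
#' @param seed RNG seed.
#' @return `(horizon + 1) x 5` matrix of occupancy proportions.
#' @export
microsimulate_cohort <- function(spec, slice, n_walkers = 200000, seed = 1L) {
  stopifnot(inherits(spec, "markov_spec"))
  set.seed(seed)
  ages <- spec$baseline_age:(spec$end_age - 1L)
  state <- rep(1L, n_walkers)  # ND
  occ <- matrix(0, spec$horizon + 1L, 5, dimnames = list(NULL, STATES))
  occ[1, ] <- tabulate(state, 5) / n_walkers
  for (t in seq_len(spec$horizon)) {
    row <- slice[slice$age == ages[t], ]
    if (!nrow(row)) stopf("missing probability slice for age %d", ages[t])
    u <- runif(n_walkers)
    new_state <- state
    nondis <- state %in% c(1L, 3L)
    dis <- state %in% c(2L, 4L)
    s <- state[nondis]
    un <- u[nondis]
    s[un < row$onset] <- 2L
    s[un >= row$onset & un < row$onset + row$die_nd] <- 5L
    new_state[nondis] <- s
    ud <- u[dis]
    s <- rep(4L, sum(dis))
    s[ud < row$recover] <- 3L
    s[ud >= row$recover & ud < row$recover + row$die_dis] <- 5L
    new_state[dis] <- s
    state <- new_state
    occ[t + 1L, ] <- tabulate(state, 5) / n_walkers
  }
  occ
}
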