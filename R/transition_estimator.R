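#' Convert a k-year probability to an annual probability
#'
#' Constant-hazard complement-root convention: `1 - (1 - p)^(1/k)`.
#'
#' @param p probability over a `k`-year interval, in `[0, 1]`.
#' @param k interval length in years (>= 1).
#' @return Annual probability.
#' @export
annualize <- function(p, k) {
  stopifnot(all(k >= 1))
  if (any(!is.finite(p)) || any(p < 0 | p > 1)) stopf("p must lie in [0, 1]")
  1 - (1 - p)^(1 / k)
}

# ---------------------------------------------------------------------------
# Annual-scale interval likelihood: the observed outcome is an event within a
# k-year interval; the annual probability is logit-linear in covariates,
# P(event in k years) = 1 - (1 - plogis(X beta))^k. With k = 1 this is exactly
# pooled logistic regression; cluster-robust (GEE-contract) variances come
# from the per-person score sandwich.
# ---------------------------------------------------------------------------

interval_neg_loglik <- function(beta, X, y, k, w) {
  p <- plogis(drop(X %*% beta))
  q <- pmax(1 - p, 1e-300)
  Pk <- pmax(1 - q^k, 1e-300)
  -sum(w * ifelse(y == 1, log(Pk), k * log(q)))
}

# per-row score factor s_i: d loglik_i / d eta_i  (loglik, not negative)
interval_score_factor <- function(beta, X, y, k, w) {
  p <- plogis(drop(X %*% beta))
  q <- pmax(1 - p, 1e-300)
  Pk <- pmax(1 - q^k, 1e-12)
  w * ifelse(y == 1, k * p * q^k / Pk, -k * p)
}

interval_neg_grad <- function(beta, X, y, k, w) {
  -drop(crossprod(X, interval_score_factor(beta, X, y, k, w)))
}

# Fit one transition model. Returns coefficients on the annual logit scale,
# cluster-robust covariance, and bookkeeping flags.
fit_interval_model <- function(X, y, k, w, cluster) {
  events <- sum(w * y)
  n <- length(y)
  if (events <= 0) {
    return(list(coef = setNames(rep(NA_real_, ncol(X)), colnames(X)),
                vcov = matrix(NA_real_, ncol(X), ncol(X)),
                n = n, events = 0, p_zero = TRUE, converged = TRUE))
  }
  # start values: naive logistic on the interval outcome, intercept shifted to
  # the annual scale
  start <- tryCatch({
    g <- suppressWarnings(glm.fit(X, y, weights = w, family = binomial()))
    b <- coef(g)
    b[1] <- b[1] - log(mean(k))
    b[!is.finite(b)] <- 0
    b
  }, error = function(e) c(qlogis(clip01(events / sum(w * k))), rep(0, ncol(X) - 1)))
  opt <- optim(start, interval_neg_loglik, interval_neg_grad,
               X = X, y = y, k = k, w = w,
               method = "BFGS", control = list(maxit = 500, reltol = 1e-12))
  beta <- opt$par
  H <- optimHess(beta, interval_neg_loglik, interval_neg_grad,
                 X = X, y = y, k = k, w = w)
  bread <- tryCatch(solve(H), error = function(e) MASS::ginv(H))
  sc <- interval_score_factor(beta, X, y, k, w) * X
  sc_cl <- rowsum(sc, cluster)
  meat <- crossprod(sc_cl)
  V <- bread %*% meat %*% bread
  list(coef = setNames(beta, colnames(X)), vcov = V, n = n,
       events = events, p_zero = FALSE, converged = opt$convergence == 0)
}

#' Inverse-probability-of-response weights for wave nonresponse
#'
#' Logistic model of the probability of a complete (responded) follow-up
#' wave given age, sex, disability status at the previous observed wave, and
#' whether the previous wave was responded to. The attached weight for each
#' complete person-wave is the reciprocal of the predicted probability;
#' baseline waves (always complete by design) get weight 1. If the response
#' model separates, a ridge-penalized fit is used (with a warning).
#'
#' @param panel a `disability_panel`.
#' @return An object of class `ipw_model`: list with the fitted
#'   coefficients, a `weights` data.frame (`person_id`, `wave`, `ipw`), and
#'   a `all_complete` flag.
#' @export
fit_ipw <- function(panel) {
  d <- data.table::as.data.table(panel)
  data.table::setorder(d, person_id, wave)
  status <- panel_domain_status(d)
  anydis <- status[, .(disabled_any = any(disabled, na.rm = TRUE)), by = .(person_id, wave)]
  d <- merge(d, anydis, by = c("person_id", "wave"), sort = FALSE)
  data.table::setorder(d, person_id, wave)
  # last observed disability status carried forward
  d[, obs_dis := ifelse(!is.na(responded) & responded, disabled_any, NA)]
  d[, lag_dis := data.table::shift(data.table::nafill(
    data.table::fifelse(is.na(obs_dis), NA_integer_, as.integer(obs_dis)),
    type = "locf")), by = person_id]
  d[, lag_resp := data.table::shift(as.integer(!is.na(responded) & responded)),
    by = person_id]

  fit_rows <- d[wave > 0 & alive == TRUE & !is.na(responded)]
  fit_rows[is.na(lag_dis), lag_dis := 0L]

  if (nrow(fit_rows) == 0 || all(fit_rows$responded)) {
    w <- d[!is.na(responded) & responded == TRUE, .(person_id, wave, ipw = 1)]
    return(structure(list(coef = NULL, all_complete = TRUE,
                          weights = as.data.frame(w)), class = "ipw_model"))
  }

  X <- cbind(intercept = 1,
             age = fit_rows$age - 55,
             male = as.numeric(fit_rows$sex == "male"),
             lag_disabled = as.numeric(fit_rows$lag_dis),
             lag_response = as.numeric(fit_rows$lag_resp))
  y <- as.numeric(fit_rows$responded)
  fit <- suppressWarnings(glm.fit(X, y, family = binomial()))
  phat <- fit$fitted.values
  coefs <- coef(fit)
  if (!fit$converged || any(!is.finite(coefs)) ||
      any(phat < 1e-8 | phat > 1 - 1e-8)) {
    warnf("response model close to separation; using ridge-penalized fit")
    coefs <- ridge_logistic(X, y, lambda = 1e-3)
    phat <- plogis(drop(X %*% coefs))
  }
  phat <- clip01(phat, 1e-6)
  ww <- data.table::data.table(person_id = fit_rows$person_id,
                               wave = fit_rows$wave, ipw = 1 / phat)
  ww <- ww[fit_rows$responded == TRUE]
  base_w <- d[wave == 0 & !is.na(responded) & responded == TRUE,
              .(person_id, wave, ipw = 1)]
  weights <- rbind(base_w, ww)
  structure(list(coef = setNames(coefs, colnames(X)), all_complete = FALSE,
                 weights = as.data.frame(weights)), class = "ipw_model")
}

# Newton-Raphson logistic regression with a small ridge penalty; fallback for
# separated response models.
ridge_logistic <- function(X, y, lambda = 1e-3, maxit = 50) {
  beta <- rep(0, ncol(X))
  for (i in seq_len(maxit)) {
    p <- plogis(drop(X %*% beta))
    g <- crossprod(X, y - p) - lambda * beta
    W <- p * (1 - p)
    H <- crossprod(X * W, X) + diag(lambda, ncol(X))
    step <- solve(H, g)
    beta <- beta + step
    if (max(abs(step)) < 1e-10) break
  }
  setNames(drop(beta), colnames(X))
}

# Attach inverse response-probability factors: `w_death` (start-wave factor
# only) for the mortality models, whose risk set requires response at the
# interval start but whose outcome is observed for everyone, and `w_surv`
# (start x end factors) for the onset/remission models, where every row
# also required end-wave response. Mixing the two inside one risk set would
# distort the death / survival mix, so the factor choice follows the
# outcome's own selection mechanism.
apply_ipw_weights <- function(d, ipw) {
  w <- data.table::as.data.table(ipw$weights)
  ws <- data.table::copy(w)
  data.table::setnames(ws, "ipw", "ipw_start")
  d <- merge(d, ws, by = c("person_id", "wave"), all.x = TRUE, sort = FALSE)
  we <- data.table::copy(w)
  data.table::setnames(we, c("wave", "ipw"), c("end_wave", "ipw_end"))
  d <- merge(d, we, by = c("person_id", "end_wave"), all.x = TRUE, sort = FALSE)
  d[is.na(ipw_start), ipw_start := 1]
  d[is.na(ipw_end), ipw_end := 1]
  d[, w_death := weight * ipw_start]
  d[, w_surv := weight * ipw_start * ipw_end]
  d[, c("ipw_start", "ipw_end") := NULL]
  d
}

#' Fit annual transition models to person-period data
#'
#' For each domain x diabetes-group x cohort stratum, four binomial models
#' with logit link, linear age and a sex main effect, on the annual
#' probability scale (the k-year interval outcome enters through the
#' constant-hazard complement-root map, so with annual data this is exactly
#' pooled logistic regression): disability onset and death from the
#' non-disabled state, remission and death from the disabled state.
#' Standard errors are cluster-robust by person (GEE contract: point
#' estimates equal the pooled fit, variances from the per-person score
#' sandwich). Sampling weights and (optionally) IPW response weights are
#' multiplied and normalized to the analytic sample size. Persons prevalent
#' disabled at baseline in a domain are excluded from that domain's fits;
#' strata with no events get probability 0 with an infinite-variance flag.
#'
#' @param pp person-periods from [build_person_periods()].
#' @param ipw optional [fit_ipw()] result; its weight for the interval's end
#'   wave multiplies the sampling weight (death intervals, observed for
#'   everyone, keep weight from the start wave only).
#' @param age_center age at which the intercept is anchored (default 50).
#' @return An object of class `transition_fits`: per-stratum list of per-
#'   transition fits (`coef`, `vcov`, `n`, `events`, `p_zero`), plus the
#'   pooled weighted male share used for sex-adjusted margins.
#' @export
fit_transition_models <- function(pp, ipw = NULL, age_center = 50) {
  d <- data.table::as.data.table(pp)
  d <- d[baseline_prevalent == FALSE]
  d[, weight := sample_weight]
  d[, `:=`(w_surv = sample_weight, w_death = sample_weight)]
  if (!is.null(ipw)) {
    stopifnot(inherits(ipw, "ipw_model"))
    d <- apply_ipw_weights(d, ipw)
  }
  male_share <- d[, sum(weight * (sex == "male")) / sum(weight)]

  strata <- unique(d[, .(domain, diabetes_group, cohort)])
  fits <- list()
  for (i in seq_len(nrow(strata))) {
    s <- strata[i]
    sub <- d[domain == s$domain & diabetes_group == s$diabetes_group &
               cohort == s$cohort]
    for (tr in TRANSITIONS) {
      rows <- switch(tr,
        onset = sub[start_state == "nondis" & end_state %in% c("nondis", "dis")],
        recover = sub[start_state == "dis" & end_state %in% c("nondis", "dis")],
        die_nd = sub[start_state == "nondis"],
        die_dis = sub[start_state == "dis"]
      )
      y <- switch(tr,
        onset = as.numeric(rows$end_state == "dis"),
        recover = as.numeric(rows$end_state == "nondis"),
        die_nd = as.numeric(rows$end_state %in% "dead"),
        die_dis = as.numeric(rows$end_state %in% "dead")
      )
      if (nrow(rows) == 0) {
        fit <- list(coef = setNames(rep(NA_real_, 3),
                                    c("intercept", "age", "male")),
                    vcov = matrix(NA_real_, 3, 3), n = 0, events = 0,
                    p_zero = TRUE, converged = TRUE)
      } else {
        w <- if (tr %in% c("onset", "recover")) rows$w_surv else rows$w_death
        w <- w / mean(w)
        X <- cbind(intercept = 1, age = rows$age - age_center,
                   male = as.numeric(rows$sex == "male"))
        fit <- fit_interval_model(X, y, rows$k, w, rows$person_id)
        if (fit$p_zero) {
          message(sprintf(
            "no %s events in stratum (%s, %s, cohort %s): probability set to 0",
            tr, s$domain, s$diabetes_group, s$cohort))
        }
      }
      key <- paste(s$domain, s$diabetes_group, s$cohort, tr, sep = "|")
      fits[[key]] <- fit
    }
  }
  structure(list(fits = fits, strata = as.data.frame(strata),
                 male_share = male_share, age_center = age_center),
            class = "transition_fits")
}

# ---------------------------------------------------------------------------
# Within-interval dynamics correction.
#
# Because ND/NDH share one set of transition probabilities and STD/LTD the
# other, the latent five-state annual chain collapses to a three-state chain
# (non-disabled, disabled, dead) that is Markov on the annual clock. The
# complement-root estimand psi (what the interval ML converges to under
# biennial observation) therefore has a closed forward map h(theta) in the
# true annual probabilities theta:
#   P(dead by t+2 | N) = dn_a + (1-p_a-dn_a) dn_{a+1} + p_a dd_{a+1}
#   P(dead by t+2 | D) = dd_a + (1-r_a-dd_a) dd_{a+1} + r_a dn_{a+1}
#   P(D at t+2 | N, alive) = [p_a (1-r_{a+1}-dd_{a+1}) + (1-p_a-dn_a) p_{a+1}] / (1 - P(dead|N))
#   P(N at t+2 | D, alive) = [r_a (1-p_{a+1}-dn_{a+1}) + (1-r_a-dd_a) r_{a+1}] / (1 - P(dead|D))
# with psi = 1 - sqrt(1 - P) componentwise. predict_probability_set() inverts
# h by fixed-point iteration, de-biasing the annual probabilities that the
# complement-root convention alone would distort when remission is common.
# Matrices are draws x ages so the same code serves Monte Carlo ensembles.
# ---------------------------------------------------------------------------
# One-column forward map: annual probabilities at age a (pa, ra, dna, dda)
# and at age a+1 (pn, rn, dnn, ddn) -> implied complement-root estimands at a.
implied_naive <- function(pa, ra, dna, dda, pn, rn, dnn, ddn) {
  PdN <- dna + (1 - pa - dna) * dnn + pa * ddn
  PdD <- dda + (1 - ra - dda) * ddn + ra * dnn
  PDN <- (pa * (1 - rn - ddn) + (1 - pa - dna) * pn) / pmax(1 - PdN, 1e-12)
  PND <- (ra * (1 - pn - dnn) + (1 - ra - dda) * rn) / pmax(1 - PdD, 1e-12)
  list(onset = 1 - sqrt(pmax(1 - PDN, 0)),
       recover = 1 - sqrt(pmax(1 - PND, 0)),
       die_nd = 1 - sqrt(pmax(1 - PdN, 0)),
       die_dis = 1 - sqrt(pmax(1 - PdD, 0)))
}

# Evaluate a logit-linear curve through (a1, v1) and (a2, v2) at `ages`;
# v1, v2 are draw vectors, result is draws x length(ages).
loglinear_eval <- function(v1, v2, a1, a2, ages) {
  l1 <- qlogis(clip01(v1, 1e-12))
  l2 <- qlogis(clip01(v2, 1e-12))
  slope <- (l2 - l1) / (a2 - a1)
  plogis(outer(l1, rep(1, length(ages))) + outer(slope, ages - a1))
}

# Invert h parametrically: both the naive fits and the annual curves they
# estimate are logit-linear in age, so the inversion solves for the two
# anchor values of each transition's logit-linear annual curve such that the
# forward-mapped complement-root estimands reproduce the fitted naive values
# at the anchors. This avoids the unstable age-by-age backward recursion (the
# age-coupled system is non-normal: boundary error amplifies ~1.3x per year).
# psi: list of four draws x 2 matrices of naive values at `anchor_ages`.
# Returns corrected values in the same shape; the inner fixed point has
# contraction ~0.5 and converges in a few dozen iterations.
invert_interval_dynamics <- function(psi, anchor_ages = c(50, 70),
                                     inner_iter = 60, tol = 1e-11) {
  a1 <- anchor_ages[1]; a2 <- anchor_ages[2]
  th <- lapply(psi, function(m) clip01(m, 1e-12))
  for (it in seq_len(inner_iter)) {
    # curve values at the anchor ages and the year after each anchor
    vals <- lapply(th, function(m) {
      loglinear_eval(m[, 1], m[, 2], a1, a2, c(a1, a1 + 1, a2, a2 + 1))
    })
    resid <- 0
    for (j in 1:2) {
      at <- 2L * j - 1L  # column of the anchor itself; +1 is the next year
      impl <- implied_naive(
        vals$onset[, at], vals$recover[, at], vals$die_nd[, at], vals$die_dis[, at],
        vals$onset[, at + 1L], vals$recover[, at + 1L],
        vals$die_nd[, at + 1L], vals$die_dis[, at + 1L]
      )
      for (tr in names(th)) {
        step <- psi[[tr]][, j] - impl[[tr]]
        resid <- max(resid, max(abs(step)))
        th[[tr]][, j] <- clip01(th[[tr]][, j] + step, 1e-12)
      }
    }
    if (resid < tol) break
  }
  th
}

# Naive (complement-root) annual probabilities of a fitted stratum at the
# anchor ages, per sex; returns list of 1 x 2 matrices plus zero-event flags.
naive_anchor <- function(fits, dom, group, cohort, sex, anchor_ages) {
  out <- list()
  p_zero <- logical(0)
  for (tr in TRANSITIONS) {
    key <- paste(dom, group, cohort, tr, sep = "|")
    f <- fits$fits[[key]]
    if (is.null(f)) stopf("no fitted model for stratum %s", key)
    p_zero[tr] <- isTRUE(f$p_zero)
    if (f$p_zero) {
      out[[tr]] <- matrix(0, 1, 2)
    } else {
      eta <- f$coef[["intercept"]] +
        f$coef[["age"]] * (anchor_ages - fits$age_center) +
        f$coef[["male"]] * (sex == "male")
      out[[tr]] <- matrix(plogis(eta), 1, 2)
    }
  }
  attr(out, "p_zero") <- p_zero
  out
}

# proportional clip onto the row simplex: p1 + p2 <= 1
simplex_clip <- function(p1, p2, label = "") {
  tot <- p1 + p2
  bad <- tot > 1
  if (any(bad)) {
    warnf("simplex violation (%s): %d probabilities clipped proportionally",
          label, sum(bad))
    p1[bad] <- p1[bad] / tot[bad]
    p2[bad] <- p2[bad] / tot[bad]
  }
  list(p1, p2)
}

#' Predict the age-specific annual transition probability set
#'
#' Inverse-logit predictions of the fitted models at each integer age, per
#' sex, domain, diabetes group and cohort, annualized via the constant-
#' hazard convention and (by default) corrected for within-interval
#' dynamics — see the package vignette. Probabilities are clipped to the
#' row-simplex constraint with a warning if violated. Ages outside the
#' fitted support trigger an extrapolation warning.
#'
#' @param fits a [fit_transition_models()] result.
#' @param ages integer prediction ages (default 50:70).
#' @param correct apply the within-interval dynamics correction.
#' @return Tidy `transition_probability_set` data.frame: `age`, `sex`,
#'   `diabetes_group`, `cohort`, `domain`, `transition`, `p`, `se_logit`
#'   (delta-method, on the logit scale, from the cluster-robust covariance).
#' @export
predict_probability_set <- function(fits, ages = 50:70, correct = TRUE) {
  stopifnot(inherits(fits, "transition_fits"))
  if (min(ages) < 50 || max(ages) > 70) {
    warnf("prediction ages outside the fitted 50-70 support: extrapolating")
  }
  anchors <- c(50, 70)
  out <- list()
  for (i in seq_len(nrow(fits$strata))) {
    s <- fits$strata[i, ]
    for (sex in SEXES) {
      psi <- naive_anchor(fits, s$domain, s$diabetes_group, s$cohort, sex, anchors)
      p_zero <- attr(psi, "p_zero")
      th <- if (correct) invert_interval_dynamics(psi, anchors) else psi
      vals <- lapply(th, function(m) {
        drop(loglinear_eval(m[, 1], m[, 2], anchors[1], anchors[2], ages))
      })
      for (tr in TRANSITIONS) if (p_zero[[tr]]) vals[[tr]][] <- 0
      p_on <- vals$onset; p_re <- vals$recover
      p_dn <- vals$die_nd; p_dd <- vals$die_dis
      cl <- simplex_clip(p_on, p_dn, "onset + die_nd")
      p_on <- cl[[1]]; p_dn <- cl[[2]]
      cl <- simplex_clip(p_re, p_dd, "recover + die_dis")
      p_re <- cl[[1]]; p_dd <- cl[[2]]
      pmat <- cbind(onset = p_on, recover = p_re, die_nd = p_dn, die_dis = p_dd)
      for (tr in TRANSITIONS) {
        key <- paste(s$domain, s$diabetes_group, s$cohort, tr, sep = "|")
        f <- fits$fits[[key]]
        se <- if (f$p_zero || anyNA(f$vcov)) {
          rep(if (f$p_zero) Inf else NA_real_, length(ages))
        } else {
          xa <- cbind(1, ages - fits$age_center, as.numeric(sex == "male"))
          sqrt(pmax(rowSums((xa %*% f$vcov) * xa), 0))
        }
        out[[length(out) + 1L]] <- data.frame(
          age = ages, sex = sex, diabetes_group = s$diabetes_group,
          cohort = s$cohort, domain = s$domain, transition = tr,
          p = unname(pmat[, tr]), se_logit = se
        )
      }
    }
  }
  res <- do.call(rbind, out)
  class(res) <- c("transition_probability_set", "data.frame")
  res
}

#' Grouped annual rates per 100 person-years (report-table layout)
#'
#' Annual incidence of disability, remission, and mortality by disability
#' state for age bands 50-60, 61-70 and total, per domain, diabetes group
#' and cohort, adjusted for sex via predicted margins at the pooled
#' (weighted) sex distribution, with normal-approximation 95% confidence
#' intervals from the cluster-robust variances. Band fits are
#' intercept-plus-sex interval ML fits on the annual scale; the
#' within-interval dynamics correction is applied jointly to the four
#' margins of each band (constant-age version of the forward map).
#'
#' @param pp person-periods from [build_person_periods()].
#' @param ipw optional [fit_ipw()] result.
#' @param bands list of `c(lo, hi)` age bands for the interval-start age.
#' @param correct apply the within-interval dynamics correction.
#' @param level confidence level.
#' @return data.frame: `domain`, `diabetes_group`, `cohort`, `band`,
#'   `transition`, `rate` (per 100 person-years), `lo`, `hi`, `n`, `events`.
#' @export
grouped_annual_rates <- function(pp, ipw = NULL,
                                 bands = list(c(50, 60), c(61, 70), c(50, 70)),
                                 correct = TRUE, level = 0.95) {
  d <- data.table::as.data.table(pp)
  d <- d[baseline_prevalent == FALSE]
  d[, weight := sample_weight]
  d[, `:=`(w_surv = sample_weight, w_death = sample_weight)]
  if (!is.null(ipw)) {
    stopifnot(inherits(ipw, "ipw_model"))
    d <- apply_ipw_weights(d, ipw)
  }
  male_share <- d[, sum(weight * (sex == "male")) / sum(weight)]
  z <- qnorm(1 - (1 - level) / 2)

  strata <- unique(d[, .(domain, diabetes_group, cohort)])
  out <- list()
  for (i in seq_len(nrow(strata))) {
    s <- strata[i]
    sub <- d[domain == s$domain & diabetes_group == s$diabetes_group &
               cohort == s$cohort]
    for (b in bands) {
      bsub <- sub[age >= b[1] & age <= b[2]]
      cell <- list()
      for (tr in TRANSITIONS) {
        rows <- switch(tr,
          onset = bsub[start_state == "nondis" & end_state %in% c("nondis", "dis")],
          recover = bsub[start_state == "dis" & end_state %in% c("nondis", "dis")],
          die_nd = bsub[start_state == "nondis"],
          die_dis = bsub[start_state == "dis"]
        )
        y <- switch(tr,
          onset = as.numeric(rows$end_state == "dis"),
          recover = as.numeric(rows$end_state == "nondis"),
          die_nd = as.numeric(rows$end_state %in% "dead"),
          die_dis = as.numeric(rows$end_state %in% "dead")
        )
        if (nrow(rows) == 0) {
          cell[[tr]] <- list(p = NA_real_, se = NA_real_, n = 0, events = 0)
          message(sprintf("empty cell: %s %s cohort %s band %d-%d %s",
                          s$domain, s$diabetes_group, s$cohort, b[1], b[2], tr))
          next
        }
        w <- if (tr %in% c("onset", "recover")) rows$w_surv else rows$w_death
        w <- w / mean(w)
        X <- cbind(intercept = 1, male = as.numeric(rows$sex == "male"))
        f <- fit_interval_model(X, y, rows$k, w, rows$person_id)
        if (f$p_zero) {
          cell[[tr]] <- list(p = 0, se = 0, n = f$n, events = 0)
          next
        }
        pf <- plogis(f$coef[["intercept"]])
        pm <- plogis(f$coef[["intercept"]] + f$coef[["male"]])
        pbar <- (1 - male_share) * pf + male_share * pm
        gr <- c((1 - male_share) * pf * (1 - pf) + male_share * pm * (1 - pm),
                male_share * pm * (1 - pm))
        se <- sqrt(max(drop(gr %*% f$vcov %*% gr), 0))
        cell[[tr]] <- list(p = pbar, se = se, n = f$n, events = f$events)
      }
      ps <- vapply(cell, function(x) x$p, 0)
      if (correct && !anyNA(ps)) {
        psi <- lapply(ps, function(v) matrix(v, 1, 2))  # flat in age
        names(psi) <- TRANSITIONS
        th <- invert_interval_dynamics(psi)
        ps_corr <- vapply(th, function(m) m[1, 1], 0)
        ps_corr[ps == 0] <- 0
      } else {
        ps_corr <- ps
      }
      for (tr in TRANSITIONS) {
        ci_half <- z * cell[[tr]]$se * 100
        out[[length(out) + 1L]] <- data.frame(
          domain = s$domain, diabetes_group = s$diabetes_group,
          cohort = s$cohort, band = sprintf("%d-%d", b[1], b[2]),
          transition = tr, rate = 100 * ps_corr[[tr]],
          lo = max(100 * ps_corr[[tr]] - ci_half, 0),
          hi = 100 * ps_corr[[tr]] + ci_half,
          n = cell[[tr]]$n, events = cell[[tr]]$events
        )
      }
    }
  }
  do.call(rbind, out)
}
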