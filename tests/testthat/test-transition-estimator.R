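test_that("annualize applies the constant-hazard complement-root convention", {
  expect_equal(annualize(0, 2), 0)
  expect_equal(annualize(0.19, 2), 0.1)          # 1 - sqrt(0.81)
  expect_equal(annualize(1, 2), 1)               # absorbing
  expect_equal(annualize(0.5, 1), 0.5)
  expect_error(annualize(1.2, 2), "0, 1")
})

test_that("with annual intervals the interval ML equals pooled logistic with cluster-robust SEs", {
  skip_if_not_installed("sandwich")
  set.seed(101)
  n_cl <- 400
  cl <- rep(seq_len(n_cl), each = 3)
  age <- runif(length(cl), 50, 70)
  male <- rbinom(length(cl), 1, 0.5)
  u <- rnorm(n_cl)[cl] * 0.3   # shared cluster effect: robust SEs must differ
  y <- rbinom(length(cl), 1, plogis(-2 + 0.05 * (age - 50) + 0.3 * male + u))
  X <- cbind(intercept = 1, age = age - 50, male = male)
  fit <- disablife:::fit_interval_model(X, y, k = rep(1, length(y)),
                                        w = rep(1, length(y)), cluster = cl)
  gl <- glm(y ~ I(age - 50) + male, family = binomial())
  expect_equal(unname(fit$coef), unname(coef(gl)), tolerance = 1e-5)
  V <- sandwich::vcovCL(gl, cluster = cl, type = "HC0", cadjust = FALSE)
  expect_equal(unname(fit$vcov), unname(V), tolerance = 1e-4)
})

test_that("transition model recovers a known logit-linear onset curve", {
  # annual onset logit(p) = -3 + 0.05 (age - 50); no remission or mortality,
  # so the biennial observation maps exactly through the complement-root
  curves <- do.call(rbind, lapply(c("diabetes", "no_diabetes"), function(g) {
    data.frame(diabetes_group = g,
               transition = c("onset", "recover", "die_nd", "die_dis"),
               intercept = c(-3, rep(qlogis(1e-12), 3)),
               slope = c(0.05, 0, 0, 0), male = 0)
  }))
  cfg <- synthetic_config(20000, cohort = 1, seed = 61, true_curves = curves,
                          diabetes_prevalence = 0, diabetes_annual_incidence = 0,
                          baseline_disability_prevalence =
                            c(diabetes = 0, no_diabetes = 0))
  pp <- build_person_periods(simulate_panel(cfg), domains = "mobility")
  fits <- fit_transition_models(pp)
  b <- fits$fits[["mobility|no_diabetes|1|onset"]]$coef
  expect_lt(abs(b[["intercept"]] - (-3)), 0.1)
  expect_lt(abs(b[["age"]] - 0.05), 0.01)
  # fitted onset probabilities increase with age (positive slope passes through)
  probs <- predict_probability_set(fits)
  p_on <- probs$p[probs$transition == "onset" & probs$sex == "female"]
  expect_true(all(diff(p_on) > 0))
})

test_that("weight handling: duplication with half weight and rescaling are no-ops", {
  cfg <- flat_config(1500, seed = 71)
  pp <- build_person_periods(simulate_panel(cfg), domains = "mobility")
  fits1 <- fit_transition_models(pp)
  pp2 <- rbind(pp, pp)
  pp2$sample_weight <- pp2$sample_weight / 2
  fits2 <- fit_transition_models(pp2)
  for (key in names(fits1$fits)) {
    expect_equal(fits1$fits[[key]]$coef, fits2$fits[[key]]$coef,
                 tolerance = 1e-6)
  }
  r1 <- grouped_annual_rates(pp)
  pp3 <- data.table::copy(pp)
  pp3$sample_weight <- pp3$sample_weight * 5
  r3 <- grouped_annual_rates(pp3)
  expect_equal(r1$rate, r3$rate, tolerance = 1e-8)
})

test_that("zero-event strata yield probability zero with a log message", {
  cfg <- flat_config(400, seed = 81, p = c(onset = 0.08, recover = 0,
                                           die_nd = 0, die_dis = 0))
  pp <- build_person_periods(simulate_panel(cfg), domains = "mobility")
  expect_message(fits <- fit_transition_models(pp), "no recover events")
  probs <- predict_probability_set(fits)
  expect_true(all(probs$p[probs$transition == "recover"] == 0))
  expect_true(all(is.infinite(probs$se_logit[probs$transition == "recover"])))
})

test_that("IPW weights are reciprocals of fitted response probabilities", {
  # fully-observed panel: all weights exactly 1
  cfg <- flat_config(300, seed = 91)
  pan <- simulate_panel(cfg)
  ipw <- fit_ipw(pan)
  expect_true(ipw$all_complete)
  expect_true(all(ipw$weights$ipw == 1))

  # with nonresponse: weights >= 1, equal to 1 / plogis(model score)
  cfg2 <- synthetic_config(3000, cohort = 1, seed = 92,
                           diabetes_prevalence = 0,
                           diabetes_annual_incidence = 0,
                           missingness = default_missingness())
  pan2 <- simulate_panel(cfg2)
  ipw2 <- fit_ipw(pan2)
  expect_false(ipw2$all_complete)
  expect_true(all(ipw2$weights$ipw >= 1))
  expect_equal(sort(unique(ipw2$weights$ipw[ipw2$weights$wave == 0])), 1)
  # the response model recovers the generating mechanism's direction
  expect_lt(ipw2$coef[["age"]], 0)
  expect_gt(ipw2$coef[["lag_response"]], 0)
})

test_that("within-interval dynamics inversion round-trips the forward map", {
  anchors <- c(50, 70)
  for (case in 1:4) {
    set.seed(case)
    th_true <- list(
      onset = matrix(runif(2, 0.02, 0.10), 1),
      recover = matrix(runif(2, 0.10, 0.30), 1),
      die_nd = matrix(runif(2, 0.005, 0.04), 1),
      die_dis = matrix(runif(2, 0.01, 0.08), 1)
    )
    # forward map: implied naive estimands at the two anchors
    vals <- lapply(th_true, function(m) {
      disablife:::loglinear_eval(m[, 1], m[, 2], anchors[1], anchors[2],
                                 c(50, 51, 70, 71))
    })
    psi <- lapply(setNames(names(th_true), names(th_true)), function(tr) {
      out <- matrix(0, 1, 2)
      for (j in 1:2) {
        at <- 2 * j - 1
        out[1, j] <- disablife:::implied_naive(
          vals$onset[, at], vals$recover[, at], vals$die_nd[, at],
          vals$die_dis[, at], vals$onset[, at + 1], vals$recover[, at + 1],
          vals$die_nd[, at + 1], vals$die_dis[, at + 1])[[tr]]
      }
      out
    })
    th_hat <- disablife:::invert_interval_dynamics(psi, anchors)
    for (tr in names(th_true)) {
      expect_equal(th_hat[[tr]], th_true[[tr]], tolerance = 1e-7)
    }
  }
})

test_that("predicted probability sets respect the simplex with clipping", {
  # hand-built fits whose onset and mortality sum beyond 1
  mk_fit <- function(p) list(coef = c(intercept = qlogis(p), age = 0, male = 0),
                             vcov = diag(1e-6, 3), n = 100, events = 50,
                             p_zero = FALSE, converged = TRUE)
  fits <- structure(list(
    fits = setNames(
      list(mk_fit(0.6), mk_fit(0.2), mk_fit(0.6), mk_fit(0.1)),
      paste("mobility", "diabetes", 1, c("onset", "recover", "die_nd", "die_dis"),
            sep = "|")
    ),
    strata = data.frame(domain = "mobility", diabetes_group = "diabetes",
                        cohort = 1),
    male_share = 0.5, age_center = 50
  ), class = "transition_fits")
  warns <- testthat::capture_warnings(
    probs <- predict_probability_set(fits, correct = FALSE))
  expect_true(any(grepl("simplex", warns)))
  on <- probs$p[probs$transition == "onset"]
  dn <- probs$p[probs$transition == "die_nd"]
  expect_true(all(on + dn <= 1 + 1e-12))
  expect_equal(unique(on / dn), 1)  # proportional clip preserves the ratio

  # intercept-only model at logit 0 predicts one half everywhere
  fits$fits <- lapply(fits$fits, function(f) mk_fit(0.25))
  fits$fits[["mobility|diabetes|1|onset"]]$coef <- c(intercept = 0, age = 0, male = 0)
  p <- predict_probability_set(fits, correct = FALSE)
  expect_true(all(p$p[p$transition == "onset"] == 0.5))
})

test_that("grouped annual rates match flat generating constants within the CI", {
  cfg <- flat_config(20000, seed = 55)
  pp <- build_person_periods(simulate_panel(cfg), domains = "mobility")
  rates <- grouped_annual_rates(pp, bands = list(c(50, 70)))
  for (tr in names(TABLE_POINT)) {
    row <- rates[rates$transition == tr, ]
    half <- (row$hi - row$lo) / 2
    expect_lt(abs(row$rate - 100 * TABLE_POINT[[tr]]), half)
  }
})
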