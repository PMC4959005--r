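test_that("percentile CIs are empirical percentiles with guard rails", {
  expect_equal(percentile_ci(rep(3.5, 200)), c(3.5, 3.5))
  x <- (1:10000) / 10000
  ci <- percentile_ci(x)
  expect_lt(abs(ci[1] - 0.025), 1e-3)
  expect_lt(abs(ci[2] - 0.975), 1e-3)
  expect_error(percentile_ci(1:50), "100 draws")
  set.seed(1)
  y <- rnorm(500)
  ci2 <- percentile_ci(y)
  med <- median(y)
  expect_true(ci2[1] <= med && med <= ci2[2])
})

test_that("Monte Carlo contrasts difference, bound, and p-value correctly", {
  set.seed(2)
  a <- rnorm(1000)
  # identical ensembles: zero difference, p capped at 1
  same <- mc_contrast(a, a)
  expect_equal(same$difference, 0)
  expect_equal(same$p_value, 1)

  # published life-years-lost points: 2.8 -> 1.5 and 1.6 -> 1.3
  c1 <- mc_contrast(a + 1.5, a + 2.8, point_b = 1.5, point_a = 2.8)
  expect_equal(c1$difference, -1.3)
  c2 <- mc_contrast(a + 1.3, a + 1.6, point_b = 1.3, point_a = 1.6)
  expect_equal(c2$difference, -0.3, tolerance = 1e-12)

  # antisymmetry and the 2/n p-value floor
  b <- rnorm(1000, 0.1)
  ab <- mc_contrast(a, b)
  ba <- mc_contrast(b, a)
  expect_equal(ab$difference, -ba$difference)
  sep <- mc_contrast(a + 100, a)
  expect_equal(sep$p_value, 2 / 1000)
  expect_error(mc_contrast(a, a[1:10]), "draw counts")
})

test_that("delay ranges across domains reproduce the published example", {
  onset_c1 <- c(mobility = 63.0, iadl = 63.5, adl = 62.7)
  onset_c2 <- c(mobility = 64.8, iadl = 64.3, adl = 65.0)
  d <- delay_range(onset_c1, onset_c2)
  expect_equal(unname(d$delays[c("mobility", "iadl", "adl")]),
               c(1.8, 0.8, 2.3), tolerance = 1e-12)
  expect_equal(d$range, c(0.8, 2.3), tolerance = 1e-12)

  same <- delay_range(onset_c1, onset_c1)
  expect_equal(same$range, c(0, 0))
  # permuting the domain order leaves the range unchanged
  perm <- delay_range(onset_c1[c(3, 1, 2)], onset_c2[c(2, 3, 1)])
  expect_equal(perm$range, d$range)
  expect_error(delay_range(onset_c1[1:2], onset_c2[1:2]), "three domains")
})

test_that("percent change matches the published obesity arithmetic", {
  expect_equal(percent_change(6.4, 14.3), 123)   # class III obesity
  expect_equal(percent_change(10.7, 18.5), 73)   # class II obesity
  expect_equal(percent_change(5, 5), 0)
  expect_equal(percent_change(8, 10, digits = 1), 25)
  expect_error(percent_change(0, 5), "baseline")
})

test_that("probability draws are reproducible, valid, and centred on the point", {
  cfg <- flat_config(2500, seed = 17)
  pp <- build_person_periods(simulate_panel(cfg), domains = "mobility")
  fits <- fit_transition_models(pp)
  e1 <- draw_probability_sets(fits, n_draws = 400, seed = 3)
  e2 <- draw_probability_sets(fits, n_draws = 400, seed = 3)
  expect_identical(e1$draws, e2$draws)
  key <- "mobility|no_diabetes|1|female"
  for (tr in c("onset", "recover", "die_nd", "die_dis")) {
    m <- e1$draws[[key]][[tr]]
    expect_true(all(m >= 0 & m <= 1))
  }
  # ensemble mean within Monte Carlo error of the point prediction
  pt <- e1$point
  p_pt <- pt$p[pt$sex == "female" & pt$transition == "onset"]
  dm <- colMeans(e1$draws[[key]]$onset)
  dse <- apply(e1$draws[[key]]$onset, 2, sd) / sqrt(400)
  expect_true(all(abs(dm - p_pt) <= 3 * dse + 1e-4))
  # simplex respected draw-wise
  tot <- e1$draws[[key]]$onset + e1$draws[[key]]$die_nd
  expect_true(all(tot <= 1 + 1e-12))

  # degenerate covariance: every draw equals the point estimate
  fits0 <- fits
  for (k in names(fits0$fits)) fits0$fits[[k]]$vcov <- matrix(0, 3, 3)
  e0 <- draw_probability_sets(fits0, n_draws = 120, seed = 4)
  on0 <- e0$draws[[key]]$onset
  expect_lt(max(apply(on0, 2, sd)), 1e-12)
})

test_that("draw propagation agrees with the matrix engine and conserves years", {
  cfg <- flat_config(2500, seed = 17)
  pp <- build_person_periods(simulate_panel(cfg), domains = "mobility")
  fits <- fit_transition_models(pp)
  ens <- draw_probability_sets(fits, n_draws = 150, seed = 5)
  met <- lifetable_ensemble(ens, baseline_ages = c(50, 60))
  expect_equal(met$dfy + met$dy + met$lyl,
               ifelse(met$baseline_age == 50, 20, 10), tolerance = 1e-9)
  expect_equal(met$onset_age, met$baseline_age + met$dfy, tolerance = 1e-12)

  # the vectorized propagation must match run_cohort on the point set
  probs <- predict_probability_set(fits)
  pop <- run_population(probs, baseline_ages = 50)
  pt_draw <- list(
    onset = matrix(probs$p[probs$transition == "onset" & probs$sex == "male"], 1),
    recover = matrix(probs$p[probs$transition == "recover" & probs$sex == "male"], 1),
    die_nd = matrix(probs$p[probs$transition == "die_nd" & probs$sex == "male"], 1),
    die_dis = matrix(probs$p[probs$transition == "die_dis" & probs$sex == "male"], 1)
  )
  via_draws <- disablife:::propagate_draws(pt_draw, 50:70, 50)
  via_engine <- pop[pop$sex == "male" & pop$diabetes_group == "no_diabetes", ]
  expect_equal(via_draws$dfy, via_engine$dfy, tolerance = 1e-10)
  expect_equal(via_draws$lyl, via_engine$lyl, tolerance = 1e-10)
})

test_that("contrast p-values are calibrated under the null of no cohort change", {
  # two independent panels from identical generating curves: the share of
  # p < 0.05 stays near the nominal rate and p-values centre near one half
  one_null_p <- function(s) {
    dfy <- list()
    for (j in 1:2) {
      cfg <- synthetic_config(1500, cohort = 1, seed = s * 19 + j,
                              diabetes_prevalence = 0,
                              diabetes_annual_incidence = 0)
      pp <- build_person_periods(simulate_panel(cfg), domains = "mobility")
      fits <- fit_transition_models(pp)
      ens <- draw_probability_sets(fits, n_draws = 400, seed = s * 23 + j)
      met <- lifetable_ensemble(ens, baseline_ages = 50)
      dfy[[j]] <- met$dfy[met$sex == "male"]
    }
    mc_contrast(dfy[[2]], dfy[[1]])$p_value
  }
  pv <- vapply(1:40, one_null_p, 0)
  expect_lte(mean(pv < 0.05), 0.15)
  expect_gt(mean(pv), 0.34)
  expect_lt(mean(pv), 0.66)
})

test_that("report tables have the published shape and render deterministically", {
  grid <- expand.grid(
    sex = c("male", "female"), diabetes_group = c("diabetes", "no_diabetes"),
    cohort = 1:2, domain = c("mobility", "iadl", "adl"),
    baseline_age = c(50, 60), stringsAsFactors = FALSE
  )
  set.seed(6)
  for (m in c("dfy", "dy", "lyl", "tle", "onset_age")) {
    grid[[m]] <- round(runif(nrow(grid), 1, 15), 2)
    grid[[paste0(m, "_lo")]] <- grid[[m]] - 0.5
    grid[[paste0(m, "_hi")]] <- grid[[m]] + 0.5
  }
  dir1 <- file.path(tempdir(), "rep1")
  dir2 <- file.path(tempdir(), "rep2")
  render_tables(grid, dir = dir1)
  render_tables(grid, dir = dir2)
  men <- read.csv(file.path(dir1, "lifetable_male.csv"))
  # 12 summary rows per cohort: 3 domains x 2 baseline ages x 2 groups
  expect_equal(nrow(men[men$cohort == 1, ]), 12)
  expect_equal(nrow(men), 24)
  expect_identical(readBin(file.path(dir1, "lifetable_male.csv"), "raw", 1e6),
                   readBin(file.path(dir2, "lifetable_male.csv"), "raw", 1e6))
})
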