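test_that("degenerate configurations behave as designed", {
  # no hazards: everyone stays alive and non-disabled at every wave
  pan <- simulate_panel(zero_hazard_config(n = 40, seed = 3))
  expect_true(all(pan$alive))
  expect_true(all(is.na(pan$death_year)))
  st <- classify_domain(as.matrix(pan[, paste0("mob", 1:5), with = FALSE]),
                        "mobility")
  expect_false(any(st$disabled))

  # certain death from the non-disabled state: nobody reaches wave 1 alive
  cfg <- synthetic_config(
    30, cohort = 1, seed = 4,
    true_curves = constant_curves(0, 0, 1 - 1e-12, 0),
    diabetes_prevalence = 0, diabetes_annual_incidence = 0,
    baseline_disability_prevalence = c(diabetes = 0, no_diabetes = 0)
  )
  pan2 <- simulate_panel(cfg)
  expect_true(all(pan2$alive[pan2$wave == 0]))
  expect_false(any(pan2$alive[pan2$wave > 0]))
})

test_that("identical seeds give identical panels, different seeds differ", {
  cfg <- synthetic_config(200, cohort = 2, seed = 77,
                          missingness = default_missingness())
  p1 <- simulate_panel(cfg)
  p2 <- simulate_panel(cfg)
  expect_identical(as.data.frame(p1), as.data.frame(p2))
  cfg2 <- synthetic_config(200, cohort = 2, seed = 78,
                           missingness = default_missingness())
  expect_false(identical(as.data.frame(p1),
                         as.data.frame(simulate_panel(cfg2))))
})

test_that("panel invariants hold: monotone death and diabetes, valid weights", {
  cfg <- synthetic_config(500, cohort = 1, seed = 12,
                          diabetes_prevalence = 0.3,
                          diabetes_annual_incidence = 0.02,
                          missingness = default_missingness())
  pan <- simulate_panel(cfg)
  expect_true(all(pan$sample_weight > 0))
  bad <- pan[, .(res = any(diff(as.integer(alive)) > 0),
                 dia = any(diff(as.integer(diabetes)) < 0)),
             by = person_id]
  expect_false(any(bad$res))  # nobody resurrects
  expect_false(any(bad$dia))  # diagnosis never un-reported
  dead <- pan[alive == FALSE]
  expect_true(all(dead$death_year <= dead$interview_year))
  # baseline ages land in the designed window
  expect_true(all(data.table::between(pan[wave == 0]$age, 50, 62)))
})

test_that("latent annual event counts reproduce the generating constants", {
  # flat curves at the published diabetic cohort-1 mobility operating point
  cfg <- flat_config(20000, seed = 21)
  pan <- simulate_panel(cfg, keep_latent = TRUE)
  lat <- attr(pan, "latent")
  s <- lat$states
  n_years <- ncol(s)
  onset_events <- at_risk <- 0
  for (j in seq_len(n_years - 1)) {
    nd <- s[, j] %in% c(1L, 3L)
    at_risk <- at_risk + sum(nd)
    onset_events <- onset_events + sum(nd & s[, j + 1] == 2L)
  }
  rate <- 100 * onset_events / at_risk
  expect_lt(abs(rate - 6.7), 0.5)  # per 100 person-years at risk
})

test_that("item-level classification reproduces the latent domain state", {
  cfg <- flat_config(2000, seed = 31)
  pan <- simulate_panel(cfg, keep_latent = TRUE)
  lat <- attr(pan, "latent")
  wave_cols <- seq(1, ncol(lat$states), by = 2)
  for (dom in c("mobility", "iadl", "adl")) {
    cols <- paste0(switch(dom, mobility = "mob", iadl = "iadl", adl = "adl"), 1:5)
    st <- classify_domain(as.matrix(pan[, cols, with = FALSE]), dom)
    latent_dis <- lat$states[cbind(pan$person_id, wave_cols[pan$wave + 1])] %in% c(2L, 4L)
    obs <- !is.na(st$disabled)
    expect_identical(st$disabled[obs], latent_dis[obs])
  }
})

test_that("invalid configurations are rejected with informative errors", {
  expect_error(
    synthetic_config(10, true_curves = constant_curves(0.6, 0.1, 0.6, 0.1)),
    "onset \\+ die_nd"
  )
  expect_error(synthetic_config(10, n_waves = 1), "n_waves")
  bad <- default_true_curves()
  bad$slope[bad$transition == "die_nd"] <- NA
  expect_error(synthetic_config(10, true_curves = bad), "die_nd")
})

test_that("ground-truth life table closure satisfies its identities", {
  cfg0 <- zero_hazard_config()
  gt50 <- ground_truth_lifetable(cfg0, "male", "no_diabetes", 50)
  expect_equal(gt50$dfy, 20)
  expect_equal(gt50$dy, 0)
  expect_equal(gt50$lyl, 0)
  expect_equal(gt50$onset_age, 70)
  gt60 <- ground_truth_lifetable(cfg0, "female", "no_diabetes", 60)
  expect_equal(gt60$dfy, 10)

  # conservation holds exactly for arbitrary configurations
  for (cohort in 1:2) {
    cfg <- synthetic_config(10, cohort = cohort, seed = 1)
    for (grp in c("diabetes", "no_diabetes")) {
      gt <- ground_truth_lifetable(cfg, "male", grp, 50)
      expect_equal(gt$dfy + gt$dy + gt$lyl, 20, tolerance = 1e-12)
    }
  }
})

test_that("panel round-trips through CSV with config sidecar", {
  cfg <- synthetic_config(30, seed = 9, missingness = default_missingness())
  pan <- simulate_panel(cfg)
  csv <- tempfile(fileext = ".csv")
  js <- tempfile(fileext = ".json")
  write_panel(pan, csv, config_path = js)
  back <- read_panel(csv)
  # the CSV carries the data; the config lives in the JSON sidecar
  expect_equal(as.data.frame(back), as.data.frame(pan), ignore_attr = TRUE)
  expect_true(file.exists(js))
  pp1 <- build_person_periods(pan)
  pp2 <- build_person_periods(back)
  expect_equal(as.data.frame(pp1), as.data.frame(pp2))
})
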