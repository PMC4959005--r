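#' Monte Carlo draws of the transition probability set
#'
#' Multivariate normal draws on the logit-coefficient scale from each fitted
#' model's cluster-robust covariance, pushed through the same
#' annualization / within-interval-dynamics correction as the point
#' predictions. Non-positive-definite covariances are repaired by flooring
#' their eigenvalues (with a warning); zero-event models contribute
#' degenerate zero draws.
#'
#' @param fits a [fit_transition_models()] result.
#' @param n_draws draws per sex (the published convention is 5,000 per sex,
#'   i.e. 10,000 in total).
#' @param seed integer RNG seed; fixed seed gives an identical ensemble.
#' @param ages integer prediction ages.
#' @param correct apply the within-interval dynamics correction.
#' @return Object of class `probability_draw_ensemble`: per stratum x sex, a
#'   list of four `n_draws x length(ages)` probability matrices, plus the
#'   point probability set.
#' @export
draw_probability_sets <- function(fits, n_draws = 5000, seed = 1L,
                                  ages = 50:70, correct = TRUE) {
  stopifnot(inherits(fits, "transition_fits"), n_draws >= 1)
  set.seed(as.integer(seed))
  anchors <- c(50, 70)
  draws <- list()
  for (i in seq_len(nrow(fits$strata))) {
    s <- fits$strata[i, ]
    coef_draws <- list()
    for (tr in TRANSITIONS) {
      key <- paste(s$domain, s$diabetes_group, s$cohort, tr, sep = "|")
      f <- fits$fits[[key]]
      if (f$p_zero) {
        coef_draws[[tr]] <- NULL
        next
      }
      V <- (f$vcov + t(f$vcov)) / 2
      ev <- eigen(V, symmetric = TRUE)
      if (any(ev$values < 0)) {
        warnf("covariance for %s repaired to nearest PD (eigenvalue floor)", key)
        V <- ev$vectors %*% diag(pmax(ev$values, 1e-12), length(ev$values)) %*%
          t(ev$vectors)
      }
      coef_draws[[tr]] <- MASS::mvrnorm(n_draws, mu = f$coef, Sigma = V)
    }
    for (sex in SEXES) {
      psi <- list()
      zero_tr <- character(0)
      for (tr in TRANSITIONS) {
        cd <- coef_draws[[tr]]
        if (is.null(cd)) {
          psi[[tr]] <- matrix(0, n_draws, 2)
          zero_tr <- c(zero_tr, tr)
        } else {
          xa <- rbind(1, anchors - fits$age_center, as.numeric(sex == "male"))
          psi[[tr]] <- plogis(cd %*% xa)
        }
      }
      th <- if (correct) invert_interval_dynamics(psi, anchors) else psi
      th <- lapply(th, function(m) {
        loglinear_eval(m[, 1], m[, 2], anchors[1], anchors[2], ages)
      })
      for (tr in zero_tr) th[[tr]][] <- 0
      # enforce the row-simplex constraint draw-wise
      tot <- th$onset + th$die_nd
      sc <- pmax(tot, 1)
      th$onset <- th$onset / sc; th$die_nd <- th$die_nd / sc
      tot <- th$recover + th$die_dis
      sc <- pmax(tot, 1)
      th$recover <- th$recover / sc; th$die_dis <- th$die_dis / sc
      key <- paste(s$domain, s$diabetes_group, s$cohort, sex, sep = "|")
      draws[[key]] <- th
    }
  }
  structure(list(draws = draws, n_draws = n_draws, ages = ages, seed = seed,
                 strata = fits$strata,
                 point = predict_probability_set(fits, ages, correct = correct)),
            class = "probability_draw_ensemble")
}

# Vectorized (over draws) cohort propagation with cycle-start accounting.
# th: list of 4 matrices n_draws x |ages|; returns data.frame of metrics.
propagate_draws <- function(th, ages, baseline_age, end_age = 70) {
  need <- baseline_age:(end_age - 1L)
  cols <- match(need, ages)
  if (anyNA(cols)) stopf("draw ensemble lacks ages %s",
                         paste(need[is.na(cols)], collapse = ", "))
  n <- nrow(th$onset)
  nd <- rep(1, n); std <- ndh <- ltd <- dead <- rep(0, n)
  dfy <- dy <- rep(0, n)
  for (j in cols) {
    dfy <- dfy + nd + ndh
    dy <- dy + std + ltd
    on <- th$onset[, j]; re <- th$recover[, j]
    dn <- th$die_nd[, j]; dd <- th$die_dis[, j]
    nd2 <- nd * (1 - on - dn)
    std2 <- (nd + ndh) * on
    ndh2 <- (std + ltd) * re + ndh * (1 - on - dn)
    ltd2 <- (std + ltd) * (1 - re - dd)
    dead2 <- dead + (nd + ndh) * dn + (std + ltd) * dd
    nd <- nd2; std <- std2; ndh <- ndh2; ltd <- ltd2; dead <- dead2
  }
  H <- end_age - baseline_age
  data.frame(draw = seq_len(n), dfy = dfy, dy = dy, tle = dfy + dy,
             lyl = H - dfy - dy, onset_age = baseline_age + dfy)
}

#' Life-table metric ensemble from probability draws
#'
#' Runs the five-state cohort model for every Monte Carlo draw and stratum.
#'
#' @param ens a [draw_probability_sets()] ensemble.
#' @param baseline_ages model entry ages.
#' @param end_age horizon end.
#' @return data.frame: `sex`, `diabetes_group`, `cohort`, `domain`,
#'   `baseline_age`, `draw`, `dfy`, `dy`, `tle`, `lyl`, `onset_age`.
#' @export
lifetable_ensemble <- function(ens, baseline_ages = c(50, 60), end_age = 70) {
  stopifnot(inherits(ens, "probability_draw_ensemble"))
  out <- list()
  for (key in names(ens$draws)) {
    parts <- strsplit(key, "|", fixed = TRUE)[[1]]
    for (ba in baseline_ages) {
      m <- propagate_draws(ens$draws[[key]], ens$ages, ba, end_age)
      m$domain <- parts[1]; m$diabetes_group <- parts[2]
      m$cohort <- as.integer(parts[3]); m$sex <- parts[4]
      m$baseline_age <- ba
      out[[length(out) + 1L]] <- m
    }
  }
  do.call(rbind, out)
}

#' Empirical percentile confidence interval
#'
#' @param x numeric vector of Monte Carlo metric values (at least 100).
#' @param level confidence level (default 0.95).
#' @return `c(low, high)`: the empirical `(1-level)/2` and `1-(1-level)/2`
#'   percentiles.
#' @export
percentile_ci <- function(x, level = 0.95) {
  if (length(x) < 100) stopf("at least 100 draws required (got %d)", length(x))
  stopifnot(level > 0, level < 1)
  a <- (1 - level) / 2
  unname(quantile(x, c(a, 1 - a), names = FALSE, type = 7))
}

#' Monte Carlo contrast between two independent ensembles
#'
#' Per-draw differences of a metric between two ensembles fitted on
#' disjoint samples (e.g. two birth cohorts, or diabetes vs no diabetes).
#' The point difference is the difference of point summaries, the CI the
#' percentile interval of the per-draw differences, and the two-sided
#' p-value `2 * min(share of differences > 0, share < 0)` (computed with
#' ties counted on both sides, capped at 1), floored at `2 / n_draws`.
#'
#' @param draws_b,draws_a equal-length draw vectors (the contrast is B - A,
#'   e.g. cohort 2 minus cohort 1).
#' @param point_b,point_a point estimates of the metric (defaults: draw
#'   means).
#' @param level confidence level.
#' @return list with `difference`, `ci` (length 2), `p_value`, `n_draws`.
#' @export
mc_contrast <- function(draws_b, draws_a, point_b = mean(draws_b),
                        point_a = mean(draws_a), level = 0.95) {
  if (length(draws_a) != length(draws_b)) {
    stopf("draw counts differ (%d vs %d)", length(draws_b), length(draws_a))
  }
  d <- draws_b - draws_a
  n <- length(d)
  p <- min(1, 2 * min(mean(d >= 0), mean(d <= 0)))
  p <- max(p, 2 / n)
  list(difference = point_b - point_a, ci = percentile_ci(d, level),
       p_value = p, n_draws = n)
}

#' Range of cohort onset-age delays across disability domains
#'
#' Per-domain difference in average onset age (cohort 2 minus cohort 1) and
#' its range across the three domains — the "x to y year delay in
#' disability" summary.
#'
#' @param onset_c1,onset_c2 named numeric vectors (names = domains) of
#'   average onset ages in the same stratum.
#' @return list with `delays` (named per domain) and `range` = `c(min, max)`.
#' @export
delay_range <- function(onset_c1, onset_c2) {
  if (is.null(names(onset_c1)) || is.null(names(onset_c2))) {
    stopf("onset ages must be named by domain")
  }
  if (!setequal(names(onset_c1), names(onset_c2)) ||
      !all(DOMAINS %in% names(onset_c1))) {
    stopf("onset ages must cover all three domains in both cohorts")
  }
  delays <- onset_c2[names(onset_c1)] - onset_c1
  list(delays = delays, range = c(min(delays), max(delays)))
}

#' Percent change between a baseline and follow-up proportion
#'
#' `(followup - baseline) / baseline * 100`, rounded for reporting.
#'
#' @param baseline,followup values with `baseline > 0`.
#' @param digits rounding digits (default 0, the reporting convention).
#' @return Percent change.
#' @export
percent_change <- function(baseline, followup, digits = 0) {
  if (any(baseline <= 0)) stopf("percent change undefined for baseline <= 0")
  round((followup - baseline) / baseline * 100, digits)
}

#' Summarize a life-table ensemble with percentile intervals
#'
#' @param metrics a [lifetable_ensemble()] data.frame.
#' @param point optional data.frame of point summaries from
#'   [run_population()] with matching stratum columns; when supplied, the
#'   reported point values are the point-probability run rather than the
#'   draw means.
#' @param level confidence level.
#' @return data.frame keyed by stratum and baseline age with `<metric>`,
#'   `<metric>_lo`, `<metric>_hi` for dfy, dy, lyl, tle, onset_age.
#' @export
summarize_ensemble <- function(metrics, point = NULL, level = 0.95) {
  dt <- data.table::as.data.table(metrics)
  keys <- c("sex", "diabetes_group", "cohort", "domain", "baseline_age")
  mets <- c("dfy", "dy", "lyl", "tle", "onset_age")
  agg <- dt[, {
    res <- list()
    for (m in mets) {
      ci <- percentile_ci(.SD[[m]], level)
      res[[m]] <- mean(.SD[[m]])
      res[[paste0(m, "_lo")]] <- ci[1]
      res[[paste0(m, "_hi")]] <- ci[2]
    }
    res
  }, by = keys]
  agg <- as.data.frame(agg)
  if (!is.null(point)) {
    pt <- as.data.frame(point)
    idx <- match(do.call(paste, agg[keys]), do.call(paste, pt[keys]))
    for (m in mets) {
      ok <- !is.na(idx)
      agg[[m]][ok] <- pt[[m]][idx[ok]]
    }
  }
  agg
}

#' Write report tables (life-table summaries and contrasts)
#'
#' One CSV per sex mirroring the published layout (rows: domain x baseline
#' age, blocks: diabetes group; columns: DFY, DY, LYL, onset age, each with
#' CI), a plain-text rendering, and a contrast annex. Output is
#' deterministic: re-rendering identical inputs is byte-identical.
#'
#' @param summaries a [summarize_ensemble()] data.frame.
#' @param contrasts optional contrast data.frame (written as-is).
#' @param dir output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
render_tables <- function(summaries, contrasts = NULL, dir = ".") {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- character()
  fmt <- function(x, lo, hi) sprintf("%.1f (%.1f,%.1f)", x, lo, hi)
  for (sx in unique(summaries$sex)) {
    sub <- summaries[summaries$sex == sx, ]
    ord <- order(sub$diabetes_group, sub$cohort, sub$domain, sub$baseline_age)
    sub <- sub[ord, ]
    tab <- data.frame(
      diabetes_group = sub$diabetes_group, cohort = sub$cohort,
      domain = sub$domain, baseline_age = sub$baseline_age,
      disability_free_years = fmt(sub$dfy, sub$dfy_lo, sub$dfy_hi),
      disabled_years = fmt(sub$dy, sub$dy_lo, sub$dy_hi),
      life_years_lost = fmt(sub$lyl, sub$lyl_lo, sub$lyl_hi),
      onset_age = fmt(sub$onset_age, sub$onset_age_lo, sub$onset_age_hi)
    )
    csv <- file.path(dir, sprintf("lifetable_%s.csv", sx))
    data.table::fwrite(tab, csv)
    txt <- file.path(dir, sprintf("lifetable_%s.txt", sx))
    writeLines(c(
      sprintf("Estimated healthy and disabled years (%s), baseline age to 70", sx),
      utils::capture.output(print(tab, row.names = FALSE))
    ), txt)
    paths <- c(paths, csv, txt)
  }
  if (!is.null(contrasts)) {
    cp <- file.path(dir, "contrasts.csv")
    data.table::fwrite(as.data.frame(contrasts), cp)
    paths <- c(paths, cp)
  }
  invisible(paths)
}
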