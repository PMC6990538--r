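test_that("zero-innovation extensions are the exact linear continuation", {
  d <- toy_design()
  # period effects ending in (3, 5): next three must be 7, 9, 11
  pi0 <- c(rep(0, d$P - 2), 3, 5)
  fd <- const_draws(d, alpha = rep(1, d$A), pi = pi0, gamma = rep(2, d$C),
                    tau_period = 0, tau_cohort = 0)
  ext <- extend_effects(fd, horizon = 3, seed = 1)
  new_pi <- ext$pi[, d$P + 1:3]
  expect_true(all(new_pi[, 1] == 7 & new_pi[, 2] == 9 & new_pi[, 3] == 11))
  # constant tails stay constant
  expect_true(all(ext$gamma[, d$C + 1:3] == 2))
  # observed range untouched
  expect_equal(ext$pi[, 1:d$P, drop = FALSE],
               effect_draws(fd, "period"))
})

test_that("horizon 0 leaves the draws unchanged and negatives error", {
  d <- toy_design()
  fd <- const_draws(d, rep(0, d$A), seq_len(d$P), rep(0, d$C))
  ext <- extend_effects(fd, horizon = 0, seed = 1)
  expect_equal(ext$pi, effect_draws(fd, "period"))
  expect_equal(ext$gamma, effect_draws(fd, "cohort"))
  expect_error(extend_effects(fd, horizon = -1), "horizon")
})

test_that("stochastic extensions match RW2 predictive moments", {
  d <- toy_design()
  tr <- default_truth(d, "sbp", "male", residual_sd = 5)
  tab <- simulate_cell_table(tr, d, seed = 51)
  fit <- suppressWarnings(fit_apc(tab, d, chains = 2, iterations = 800,
                                  seed = 7, weighting = "n", max_doublings = 1))
  ext <- extend_effects(fit, horizon = 5, seed = 9)
  pi_obs <- effect_draws(fit, "period")
  J <- ncol(pi_obs)
  for (h in 1:5) {
    lin <- (1 + h) * ext$pi[, J] - h * ext$pi[, J - 1]  # per-draw linear continuation
    dev <- ext$pi[, J + h] - lin
    mcse <- sd(dev) / sqrt(length(dev))
    expect_lt(abs(mean(dev)), 3 * mcse)
  }
  # innovation variance accumulates with the step
  vars <- sapply(1:5, function(h)
    var(ext$pi[, J + h] - (1 + h) * ext$pi[, J] + h * ext$pi[, J - 1]))
  expect_true(all(diff(vars) > 0))
  # credible-interval width of the extended effects is non-decreasing in h
  widths <- apply(ext$pi[, J + 1:5], 2, function(v)
    diff(quantile(v, c(0.025, 0.975))))
  expect_true(all(diff(widths) > -1e-8))
})

test_that("projected cells are the additive sum and agree with the fit at the boundary", {
  d <- toy_design()
  alpha <- seq(100, 104, length.out = d$A)
  pi0 <- 0.5 * (seq_len(d$P) - 2)
  gamma0 <- 0.1 * (seq_len(d$C) - 5)
  fd <- const_draws(d, alpha, pi0, gamma0)
  ext <- extend_effects(fd, horizon = 2, seed = 1)
  proj <- project_cell_means(ext)
  # deterministic additive sum, zero-width intervals
  for (i in seq_len(nrow(proj$cells))) {
    cell <- proj$cells[i, ]
    a_i <- match(cell$age, d$ages)
    want <- alpha[a_i] + ext$pi[1, as.character(cell$period)] +
      ext$gamma[1, as.character(cell$cohort_index)]
    expect_equal(cell$mean, unname(want))
    expect_equal(cell$lower, cell$upper)
  }

  # projecting the final observed period reproduces the fitted cells exactly
  tr <- default_truth(d, "sbp", "male", residual_sd = 5)
  tab <- simulate_cell_table(tr, d, seed = 61)
  fit <- suppressWarnings(fit_apc(tab, d, chains = 2, iterations = 400,
                                  seed = 3, max_doublings = 0))
  ext2 <- extend_effects(fit, horizon = 1, seed = 2)
  last <- max(d$periods)
  proj2 <- project_cell_means(ext2, periods = last)
  fitted <- apctrend:::fitted_cell_draws(fit)
  sel <- which(fit$table$period == last)
  ord <- order(fit$table$age[sel])
  expect_equal(unname(proj2$draws), unname(fitted[, sel[ord]]))
})

test_that("the projection horizon covers exactly the needed future cohorts", {
  d <- bp_design()
  fd <- const_draws(d, rep(0, d$A), rep(0, d$P), rep(0, d$C))
  ext <- extend_effects(fd, horizon = 10, seed = 1)
  # ages 9-18 projected through 2024: newest cohort 2024 - 9 = 2015,
  # exactly the 10th extension beyond the last observed cohort (2005)
  expect_equal(max(ext$future_cohorts), 2015)
  proj <- project_cell_means(ext)
  expect_equal(max(proj$cells$cohort_index), 2015)
  expect_equal(max(proj$cells$cohort_label), "2014-2015")
  # horizon too short for the requested periods -> explicit error
  ext5 <- extend_effects(fd, horizon = 5, seed = 1)
  expect_error(project_cell_means(ext5, periods = 2015:2024),
               "horizon >= 10")
})

test_that("yearly series averages ages with the requested weights", {
  d <- build_design(5, 6, 2000, 2001)
  alpha <- c(10, 14)
  fd <- const_draws(d, alpha, rep(0, d$P), rep(0, d$C))
  fd$table <- data.frame(sex = "male", age = rep(d$ages, each = d$P),
                         period = rep(d$periods, d$A),
                         cohort_index = 0, cohort_label = "",
                         n = 1L,
                         mean = rep(alpha, each = d$P), sd = 0)
  ser <- yearly_mean_series(fd)
  expect_equal(ser$mean, c(12, 12))                 # equal weights
  ser2 <- yearly_mean_series(fd, age_weights = c(1, 3))
  expect_equal(ser2$mean, c(13, 13))
  ser3 <- yearly_mean_series(fd, observed = "raw")
  expect_equal(ser3$mean, c(12, 12))
  expect_true(all(is.na(ser3$lower)))
  # single age: series equals that age's cell means
  d1 <- build_design(5, 5, 2000, 2002)
  f1 <- const_draws(d1, 7, c(0, 1, 2), rep(0, d1$C))
  f1$table <- data.frame(sex = "m", age = 5, period = d1$periods,
                         cohort_index = 0, cohort_label = "", n = 1L,
                         mean = 7 + c(0, 1, 2), sd = 0)
  s1 <- yearly_mean_series(f1)
  expect_equal(s1$mean, c(7, 8, 9))
})

test_that("a projected series tracks the sign of a rising future period trend", {
  d <- toy_design()
  tr <- default_truth(d, "sbp", "male", residual_sd = 5)
  # steadily rising period effect: the RW2 continuation keeps rising
  tr$period_curve[] <- 0.8 * (d$periods - min(d$periods))
  tr$period_curve <- tr$period_curve - mean(tr$period_curve)
  tab <- simulate_cell_table(tr, d, seed = 71)
  fit <- suppressWarnings(fit_apc(tab, d, chains = 2, iterations = 600,
                                  seed = 5, weighting = "n", max_doublings = 1))
  ext <- extend_effects(fit, horizon = 4, seed = 6)
  ser <- yearly_mean_series(fit, ext)
  prj <- ser[ser$type == "projected", ]
  expect_gt(prj$mean[4] - prj$mean[1], 0)
})
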