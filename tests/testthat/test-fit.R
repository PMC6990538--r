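# penalised closed form, Gibbs sampler, R-hat, posterior summaries, DIC

test_that("unsmoothed penalised fit recovers noise-free cell means exactly", {
  d <- toy_design()
  tr <- default_truth(d, "sbp", "male", residual_sd = 0)
  tab <- truth_to_cell_means(tr, d)
  pf <- penalized_fit(tab, d, tau = Inf, sigma = 1)
  expect_lt(max(abs(pf$fitted - tab$mean)), 1e-8)
  # constraints hold exactly on the returned effect vectors
  expect_equal(unname(pf$pi[c(d$ref_period_low, d$ref_period_high)]), c(0, 0))
  expect_equal(unname(pf$gamma[d$ref_cohort]), 0)
})

test_that("tau -> 0 collapses each effect onto the RW2 null space (a line)", {
  d <- toy_design()
  tr <- default_truth(d, "sbp", "male", residual_sd = 0)
  tab <- truth_to_cell_means(tr, d)
  pf <- penalized_fit(tab, d, tau = c(age = Inf, period = 1e-4, cohort = Inf),
                      sigma = 1)
  # a line through the two zero reference periods is identically zero
  expect_lt(max(abs(pf$pi)), 1e-4)
  pf2 <- penalized_fit(tab, d, tau = c(age = 1e-4, period = Inf, cohort = Inf),
                       sigma = 1)
  expect_lt(max(abs(diff(pf2$alpha, differences = 2))), 1e-4)
})

test_that("Gibbs posterior mean matches the closed-form solution at fixed hyperparameters", {
  d <- toy_design()
  tr <- default_truth(d, "sbp", "male", residual_sd = 5)
  tab <- simulate_cell_table(tr, d, n_per_cell = 200, sd_indiv = 5, seed = 42)
  fit <- fit_apc(tab, d, chains = 5, iterations = 1000, seed = 11,
                 weighting = "n",
                 fixed = list(sigma = 5, tau = c(age = 2, period = 2, cohort = 2)))
  pf <- penalized_fit(tab, d, tau = 2, sigma = 5, weighting = "n")
  free <- fit$param_map$free & fit$param_map$effect %in% c("age", "period", "cohort")
  m <- draws_matrix(fit)[, which(free), drop = FALSE]
  # at fixed hyperparameters the draws are iid from the exact Gaussian
  # posterior, so the MC standard error is sd / sqrt(ndraws)
  z <- abs(colMeans(m) - pf$beta) / (apply(m, 2, sd) / sqrt(nrow(m)))
  expect_lt(max(z), 3)
})

test_that("sampling is deterministic given the seed and keeps constraints at zero", {
  d <- toy_design()
  tr <- default_truth(d, "sbp", "male", residual_sd = 5)
  tab <- simulate_cell_table(tr, d, seed = 7)
  f1 <- suppressWarnings(fit_apc(tab, d, chains = 2, iterations = 300,
                                 seed = 5, max_doublings = 0))
  f2 <- suppressWarnings(fit_apc(tab, d, chains = 2, iterations = 300,
                                 seed = 5, max_doublings = 0))
  expect_identical(f1$draws, f2$draws)
  pm <- f1$param_map
  con <- pm$effect %in% c("period", "cohort") & !pm$free
  expect_equal(sum(con), 3)                    # two periods + central cohort
  expect_true(all(f1$draws[, con, ] == 0))
})

test_that("fitted cell means are invariant to the corner-constraint choice", {
  d <- toy_design()
  tr <- default_truth(d, "sbp", "male", residual_sd = 5)
  tab <- simulate_cell_table(tr, d, seed = 13)
  f1 <- suppressWarnings(fit_apc(tab, d, chains = 2, iterations = 600,
                                 seed = 1, weighting = "n", max_doublings = 1))
  d2 <- d
  d2$ref_period_low <- 3L
  d2$ref_period_high <- d$P - 2L
  d2$ref_cohort <- d$ref_cohort - 2L
  f2 <- suppressWarnings(fit_apc(tab, d2, chains = 2, iterations = 600,
                                 seed = 2, weighting = "n", max_doublings = 1))
  mu1 <- colMeans(apctrend:::fitted_cell_draws(f1))
  mu2 <- colMeans(apctrend:::fitted_cell_draws(f2))
  # effect vectors differ by construction, fitted cell means agree up to
  # Monte-Carlo error (posterior sd of a cell mean here is ~0.3)
  expect_lt(max(abs(mu1 - mu2)), 0.15)
  expect_gt(max(abs(colMeans(effect_draws(f1, "period")) -
                    colMeans(effect_draws(f2, "period")))), 0.01)
})

test_that("split-chain R-hat behaves on constant, separated and iid chains", {
  arr <- array(1, c(20, 1, 3))
  expect_warning(r <- rhat(arr), "zero within-chain variance")
  expect_equal(unname(r), 1)

  sep <- array(rep(c(0, 5), each = 20), c(20, 1, 2))
  expect_equal(unname(rhat(sep)), Inf)     # far above any threshold

  set.seed(1)
  iid <- array(rnorm(500 * 5), c(500, 1, 5))
  expect_lt(rhat(iid), 1.05)
  expect_gte(rhat(iid), 0.99)   # can dip just below 1 by sampling noise
})

test_that("non-convergence is flagged with a warning, never silent", {
  d <- toy_design()
  tr <- default_truth(d, "sbp", "male", residual_sd = 5)
  tab <- simulate_cell_table(tr, d, seed = 3)
  expect_warning(
    fit <- fit_apc(tab, d, chains = 2, iterations = 8, seed = 1,
                   max_doublings = 0),
    "not converged"
  )
  expect_false(fit$converged)
})

test_that("posterior summaries give means, central intervals and R-hat", {
  d <- toy_design()
  tr <- default_truth(d, "sbp", "male", residual_sd = 5)
  tab <- simulate_cell_table(tr, d, seed = 19)
  fit <- suppressWarnings(fit_apc(tab, d, chains = 2, iterations = 400,
                                  seed = 3, max_doublings = 0))
  s <- summarize_draws(fit)
  expect_true(all(s$lower <= s$mean + 1e-12 & s$mean <= s$upper + 1e-12))
  con <- !fit$param_map$free & fit$param_map$effect %in% c("period", "cohort")
  expect_true(all(s$mean[con] == 0 & s$lower[con] == 0 & s$upper[con] == 0))

  # interval calibration on iid normal draws
  set.seed(2)
  arr <- array(rnorm(10000), c(2500, 1, 4))
  fake <- fit
  fake$draws <- arr
  fake$param_map <- data.frame(param = "z", effect = "age", level = 1,
                               free = TRUE, fixed = FALSE)
  fake$rhat <- NULL
  sz <- summarize_draws(fake)
  expect_lt(abs(sz$lower - (-1.96)), 0.08)
  expect_lt(abs(sz$upper - 1.96), 0.08)
})

test_that("DIC is Dbar + pD with pD = 0 for a degenerate posterior", {
  d <- toy_design()
  tr <- default_truth(d, "sbp", "male", residual_sd = 5)
  tab <- simulate_cell_table(tr, d, seed = 23)
  fit <- suppressWarnings(fit_apc(tab, d, chains = 2, iterations = 400,
                                  seed = 3, max_doublings = 0))
  # collapse every draw to the posterior mean -> deviance is constant
  m <- colMeans(apctrend:::draws_matrix(fit))
  fit$draws <- array(rep(m, each = 8), c(8, length(m), 2),
                     dimnames = dimnames(fit$draws)[c(1, 2, 3)])
  dd <- dic(fit)
  expect_equal(dd$pD, 0, tolerance = 1e-8)
  expect_equal(dd$DIC, dd$Dbar, tolerance = 1e-8)
})

test_that("DIC separates models when the period signal is strong", {
  d <- toy_design()
  tr <- default_truth(d, "sbp", "male", residual_sd = 5)
  tr$period_curve[] <- 1.0 * abs(d$periods - 2003)
  tr$period_curve <- tr$period_curve - mean(tr$period_curve)
  good <- 0
  for (r in 1:20) {
    tab <- simulate_cell_table(tr, d, n_per_cell = 200, sd_indiv = 5,
                               seed = 3000 + r)
    cm <- suppressWarnings(compare_models(tab, d, c("A", "AP"), chains = 2,
                                          iterations = 500, seed = 3000 + r,
                                          weighting = "n", max_doublings = 1))
    good <- good + (cm$DIC[cm$model == "AP"] < cm$DIC[cm$model == "A"])
  }
  expect_gte(good, 18)
})

test_that("compare_models returns one row per model and flags the minimum", {
  d <- toy_design()
  tr <- default_truth(d, "sbp", "male", residual_sd = 5)
  tab <- simulate_cell_table(tr, d, seed = 29)
  cm <- suppressWarnings(compare_models(tab, d, c("A", "AP", "AC", "APC"),
                                        chains = 2, iterations = 300,
                                        seed = 4, max_doublings = 0))
  expect_equal(nrow(cm), 4)
  expect_equal(sum(cm$best), 1)
  expect_equal(cm$model[cm$best], cm$model[which.min(cm$DIC)])
  one <- suppressWarnings(compare_models(tab, d, "A", chains = 2,
                                         iterations = 300, seed = 4,
                                         max_doublings = 0))
  expect_equal(nrow(one), 1)
})
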