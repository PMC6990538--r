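# shared fixtures: all synthetic, built in code at test time

toy_design <- function() build_design(9, 13, 2000, 2005)  # A=5, P=6, C=10

bp_design <- function() build_design(9, 18, 1999, 2014)   # A=10, P=16, C=25

bmi_design <- function() build_design(6, 18, 1996, 2014)  # A=13, P=19, C=31

# zero curves over a design's grids
flat_truth <- function(design, residual_sd = 0) {
  apc_truth(
    stats::setNames(rep(0, design$A), design$ages),
    stats::setNames(rep(0, design$P), design$periods),
    stats::setNames(rep(0, design$C), design$cohorts),
    residual_sd
  )
}

# simulate a stratum table directly at the cell-mean level: individual
# noise sd / sqrt(n_per_cell) around the truth's additive cell means
simulate_cell_table <- function(truth, design, n_per_cell = 200L,
                                sd_indiv = 5, seed = 1L) {
  tab <- truth_to_cell_means(truth, design)
  set.seed(seed)
  tab$n <- as.integer(n_per_cell)
  tab$mean <- tab$mean + stats::rnorm(nrow(tab), 0, sd_indiv / sqrt(n_per_cell))
  tab$sd <- sd_indiv
  tab
}

# minimal apc_draws object with constant draws, for deterministic-limit
# tests of the RW2 extrapolation (tau exactly 0)
const_draws <- function(design, alpha, pi, gamma, sigma = 0,
                        tau_period = 0, tau_cohort = 0,
                        ndraw = 20L, chains = 2L) {
  stopifnot(length(alpha) == design$A, length(pi) == design$P,
            length(gamma) == design$C)
  pm <- rbind(
    data.frame(param = paste0("age_", design$ages), effect = "age",
               level = design$ages, free = TRUE, fixed = FALSE),
    data.frame(param = paste0("period_", design$periods), effect = "period",
               level = design$periods, free = TRUE, fixed = FALSE),
    data.frame(param = paste0("cohort_", design$cohorts), effect = "cohort",
               level = design$cohorts, free = TRUE, fixed = FALSE),
    data.frame(param = c("sigma", "tau_age", "tau_period", "tau_cohort"),
               effect = c("sigma", "tau", "tau", "tau"),
               level = NA_integer_, free = TRUE, fixed = TRUE)
  )
  vals <- c(alpha, pi, gamma, sigma, 0, tau_period, tau_cohort)
  draws <- array(rep(vals, each = ndraw), c(ndraw, length(vals), chains),
                 dimnames = list(NULL, pm$param, paste0("chain", 1:chains)))
  structure(list(draws = draws, param_map = pm, design = design,
                 effects = c("age", "period", "cohort"),
                 table = NULL, chains = chains, iterations = 2L * ndraw,
                 burn = ndraw, seed = 0L, prior_upper = 100,
                 fixed = list(), converged = TRUE, weighting = "1"),
            class = "apc_draws")
}
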