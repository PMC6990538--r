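#' Extrapolate period and cohort effects under the RW2 predictive
#'
#' Extends each posterior draw of the period and cohort effect vectors
#' `horizon` steps forward: the h-th new effect is the linear continuation of
#' its two predecessors plus an innovation,
#' `theta[J+h] = 2 theta[J+h-1] - theta[J+h-2] + Normal(0, tau^2)`, applied
#' recursively with the draw's own innovation SD. Age effects are left
#' unchanged; observed-range values are carried over untouched. With
#' `tau = 0` the extension is the exact second-order (straight-line)
#' continuation.
#'
#' @param fit an `apc_draws` object from a fit including period and cohort
#'   effects.
#' @param horizon number of future period and cohort effects (>= 0; 10 in a
#'   typical 10-year projection).
#' @param seed integer seed for the predictive innovations.
#' @return object of class `apc_extended`: matrices `alpha` `[draw, age]`,
#'   `pi` `[draw, period]` and `gamma` `[draw, cohort]` over observed +
#'   future levels (years as column names), `sigma` per draw, the `design`,
#'   `horizon`, and the future period/cohort years.
#' @export
extend_effects <- function(fit, horizon = 10L, seed = 1L) {
  stopifnot(inherits(fit, "apc_draws"))
  if (!all(c("period", "cohort") %in% fit$effects))
    stop("extension needs a fit with period and cohort effects")
  if (horizon < 0) stop("horizon must be >= 0")
  horizon <- as.integer(horizon)
  m <- draws_matrix(fit)
  design <- fit$design

  ext <- function(theta, tau, new_levels) {
    # theta [draw, J], tau [draw]; recursive RW2 forward simulation
    J <- ncol(theta)
    out <- cbind(theta, matrix(NA_real_, nrow(theta), length(new_levels)))
    for (h in seq_along(new_levels)) {
      j <- J + h
      out[, j] <- 2 * out[, j - 1L] - out[, j - 2L] +
        stats::rnorm(nrow(theta), 0, tau)
    }
    colnames(out) <- c(colnames(theta), new_levels)
    out
  }

  set.seed(as.integer(seed))
  future_periods <- if (horizon > 0)
    max(design$periods) + seq_len(horizon) else integer(0)
  future_cohorts <- if (horizon > 0)
    max(design$cohorts) + seq_len(horizon) else integer(0)
  pi_ext <- ext(effect_draws(fit, "period"), m[, "tau_period"], future_periods)
  gamma_ext <- ext(effect_draws(fit, "cohort"), m[, "tau_cohort"], future_cohorts)

  structure(list(
    alpha = effect_draws(fit, "age"), pi = pi_ext, gamma = gamma_ext,
    sigma = m[, "sigma"], design = design, horizon = horizon,
    future_periods = future_periods, future_cohorts = future_cohorts
  ), class = "apc_extended")
}

#' Projected cell means over future periods
#'
#' For each draw, the projected mean of the (age `a`, period `p`) cell is
#' `alpha[a] + pi[p] + gamma[p - a]` using the extended period and cohort
#' effects. Periods inside the observed range reproduce the fitted cell
#' means of the underlying draws exactly.
#'
#' @param ext an [extend_effects()] result.
#' @param periods periods to project (default: the future periods of the
#'   extension). May include observed periods.
#' @param ages ages to include (default: all design ages).
#' @return object of class `apc_projection`: `cells` data.frame (age,
#'   period, cohort_index, mean, lower, upper) and the draw-level array
#'   `draws` `[draw, cell]`.
#' @export
project_cell_means <- function(ext, periods = ext$future_periods,
                               ages = ext$design$ages) {
  stopifnot(inherits(ext, "apc_extended"))
  g <- expand.grid(age = ages, period = periods, KEEP.OUT.ATTRS = FALSE)
  g <- g[order(g$period, g$age), , drop = FALSE]
  k <- g$period - g$age
  have_k <- as.integer(colnames(ext$gamma))
  missing_k <- setdiff(k, have_k)
  if (length(missing_k) > 0) {
    need <- max(missing_k) - max(ext$design$cohorts)
    stop("cohort index ", paste(missing_k, collapse = ", "),
         " not covered by the extension; extend at least ", need,
         " cohort effects (horizon >= ", need, ")")
  }
  have_p <- as.integer(colnames(ext$pi))
  if (!all(g$period %in% have_p))
    stop("period(s) ", paste(setdiff(g$period, have_p), collapse = ", "),
         " not covered by the extension")
  dr <- ext$alpha[, match(g$age, as.integer(colnames(ext$alpha))), drop = FALSE] +
    ext$pi[, match(g$period, have_p), drop = FALSE] +
    ext$gamma[, match(k, have_k), drop = FALSE]
  qs <- apply(dr, 2, stats::quantile, probs = c(0.025, 0.975), names = FALSE)
  cells <- data.frame(age = g$age, period = g$period, cohort_index = k,
                      cohort_label = cohort_label(g$age, g$period),
                      mean = colMeans(dr), lower = qs[1, ], upper = qs[2, ],
                      row.names = NULL)
  structure(list(cells = cells, draws = dr, design = ext$design),
            class = "apc_projection")
}

#' Observed and projected yearly mean series
#'
#' Collapses cell means to one value per calendar year by a weighted mean
#' across ages (equal weights by default), per draw, then summarises to a
#' posterior mean and 95% credible interval. Observed years can show either
#' the model-fitted means (default) or the raw stratum means.
#'
#' @param fit an `apc_draws` object.
#' @param ext an [extend_effects()] result for the projected years (omit for
#'   an observed-only series).
#' @param age_weights numeric vector over the design ages (normalised
#'   internally); default equal.
#' @param observed `"fitted"` (posterior fitted yearly means with CrIs) or
#'   `"raw"` (data means; no interval).
#' @param partial_years if `FALSE` (default), a year missing any requested
#'   age raises an error; if `TRUE`, the weighted mean uses the ages present.
#' @return data.frame: `year`, `mean`, `lower`, `upper`, `type`
#'   (`"observed"` / `"projected"`).
#' @export
yearly_mean_series <- function(fit, ext = NULL, age_weights = NULL,
                               observed = c("fitted", "raw"),
                               partial_years = FALSE) {
  observed <- match.arg(observed)
  stopifnot(inherits(fit, "apc_draws"))
  design <- fit$design
  wts <- if (is.null(age_weights)) rep(1, design$A) else age_weights
  stopifnot(length(wts) == design$A, all(wts >= 0), sum(wts) > 0)
  wts <- wts / sum(wts)
  names(wts) <- design$ages

  year_summary <- function(dr, g, years, type) {
    out <- lapply(years, function(yr) {
      sel <- which(g$period == yr)
      if (length(sel) < design$A && !partial_years)
        stop("year ", yr, " is missing ", design$A - length(sel),
             " age cell(s); set partial_years = TRUE to average over ",
             "the ages present")
      wy <- wts[as.character(g$age[sel])]
      wy <- wy / sum(wy)
      v <- drop(dr[, sel, drop = FALSE] %*% wy)
      data.frame(year = yr, mean = mean(v),
                 lower = stats::quantile(v, 0.025, names = FALSE),
                 upper = stats::quantile(v, 0.975, names = FALSE),
                 type = type)
    })
    do.call(rbind, out)
  }

  if (observed == "fitted") {
    tabg <- fit$table[, c("age", "period")]
    drf <- fitted_cell_draws(fit)
    obs <- year_summary(drf, tabg, sort(unique(tabg$period)), "observed")
  } else {
    tab <- fit$table
    obs <- do.call(rbind, lapply(sort(unique(tab$period)), function(yr) {
      sel <- tab$period == yr
      if (sum(sel) < design$A && !partial_years)
        stop("year ", yr, " is missing ", design$A - sum(sel), " age cell(s)")
      wy <- wts[as.character(tab$age[sel])]
      wy <- wy / sum(wy)
      data.frame(year = yr, mean = sum(tab$mean[sel] * wy), lower = NA_real_,
                 upper = NA_real_, type = "observed")
    }))
  }

  if (!is.null(ext) && ext$horizon > 0) {
    proj <- project_cell_means(ext)
    prj <- year_summary(proj$draws, proj$cells, ext$future_periods, "projected")
    out <- rbind(obs, prj)
  } else out <- obs
  rownames(out) <- NULL
  out
}
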