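#' Closed-form penalised (posterior-mode) APC fit
#'
#' At fixed residual SD `sigma` and fixed RW2 innovation SDs `tau`, the
#' posterior over the constrained effect coefficients is exactly Gaussian and
#' its mode (= mean) is the generalised ridge solution
#' `(X'WX/sigma^2 + K(tau))^{-1} X'W y / sigma^2`, where `K` stacks the
#' scaled second-difference penalties `D'D / tau_e^2` of each effect block.
#' This is the deterministic oracle used to initialise and cross-check the
#' Gibbs sampler. `tau = Inf` removes the smoothing penalty (flat prior);
#' `tau -> 0` forces each effect onto the RW2 null space, i.e. the best
#' linear function compatible with its zero constraints.
#'
#' @param table stratum table (one sex).
#' @param design an [build_design()] object.
#' @param tau RW2 innovation SD per effect: single number or named vector
#'   with elements among `age`, `period`, `cohort`. `Inf` = unpenalised.
#' @param sigma fixed residual SD (outcome units), > 0.
#' @param weighting `"1"` (model cell means directly, default) or `"n"`
#'   (precision proportional to cell count).
#' @param effects effect blocks to include.
#' @return object of class `apc_params`: list of full effect vectors
#'   (`alpha`, `pi`, `gamma`, named by year, zeros at the reference
#'   positions), `sigma`, `tau`, plus `fitted` cell means aligned with
#'   `table` rows.
#' @export
penalized_fit <- function(table, design, tau = 1, sigma = 1,
                          weighting = c("1", "n"),
                          effects = c("age", "period", "cohort")) {
  weighting <- match.arg(weighting)
  spec <- apc_model_spec(design, table, effects)
  stopifnot(sigma > 0)
  tau <- expand_tau(tau, spec$effects)
  w <- obs_weights(table, weighting)
  Kb <- penalty_mats(spec)
  K <- Reduce(`+`, Map(function(Km, t) {
    if (is.infinite(t)) Km * 0 else Km / t^2
  }, Kb, tau[spec$effects]))
  XtW <- t(spec$X * w)
  Q <- XtW %*% spec$X / sigma^2 + K
  rhs <- XtW %*% spec$y / sigma^2
  beta <- tryCatch(drop(solve(Q, rhs)),
                   error = function(e)
                     stop("singular penalised system: ", conditionMessage(e)))
  theta <- full_theta(spec, beta)
  params_from_theta(theta, sigma, tau, spec, beta)
}

expand_tau <- function(tau, effects) {
  if (length(tau) == 1L && is.null(names(tau)))
    tau <- stats::setNames(rep(tau, length(effects)), effects)
  stopifnot(all(effects %in% names(tau)), all(tau[effects] > 0))
  tau
}

params_from_theta <- function(theta, sigma, tau, spec, beta) {
  fitted <- drop(spec$X %*% beta)
  structure(list(
    alpha = theta[["age"]], pi = theta[["period"]], gamma = theta[["cohort"]],
    sigma = sigma, tau = tau, effects = spec$effects,
    beta = beta, fitted = fitted
  ), class = "apc_params")
}

#' Fit the Bayesian APC model by blocked Gibbs sampling
#'
#' The cell mean of stratum `i` is modelled as
#' `y_i ~ Normal(alpha[a_i] + pi[p_i] + gamma[p_i - a_i], sigma^2 / w_i)`
#' with `w_i = 1` by default (`weighting = "n"` sets `w_i = n_i`). Each
#' effect vector carries an RW2 smoothing prior penalising second
#' differences, with flat priors on its first two elements, and the corner
#' constraints of the design pin the second and penultimate period and the
#' central cohort at zero. `sigma` and the RW2 innovation SDs `tau` get
#' uniform(0, `prior_upper`) priors.
#'
#' Sampling alternates (i) a joint draw of all free effect coefficients from
#' their exact Gaussian full conditional and (ii) univariate slice-sampling
#' updates of `sigma` and each `tau`. Chains start from the penalised-fit
#' mode plus chain-indexed Gaussian jitter. The first half of each chain is
#' discarded as burn-in; if any split-chain R-hat among the monitored
#' parameters exceeds `rhat_threshold` the chain length is doubled (up to
#' `max_doublings` times) and, failing that, the result is flagged
#' non-converged with a warning -- never silently.
#'
#' @inheritParams penalized_fit
#' @param chains number of parallel chains (>= 2 for diagnostics; default 5).
#' @param iterations total iterations per chain (first half = burn-in).
#' @param seed integer seed; identical inputs and seed give identical draws.
#' @param prior_upper upper bound `U` of the uniform priors on `sigma` and
#'   `tau` (outcome units, default 100).
#' @param fixed optional list with elements `sigma` and/or `tau` to hold
#'   hyperparameters fixed (used by the closed-form cross-check).
#' @param rhat_threshold convergence threshold on split-chain R-hat.
#' @param max_doublings how many times to double `iterations` on
#'   non-convergence before flagging.
#' @param init_jitter SD of the chain-dispersion jitter around the
#'   penalised-fit start.
#' @return object of class `apc_draws`; see [summarize_draws()], [rhat()],
#'   [dic()].
#' @export
fit_apc <- function(table, design, effects = c("age", "period", "cohort"),
                    chains = 5L, iterations = 2000L, seed = 1L,
                    weighting = c("1", "n"), prior_upper = 100,
                    fixed = list(), rhat_threshold = 1.05,
                    max_doublings = 2L, init_jitter = 1) {
  weighting <- match.arg(weighting)
  stopifnot(chains >= 2L, iterations >= 8L)
  spec <- apc_model_spec(design, table, effects)
  w <- obs_weights(table, weighting)

  it <- as.integer(iterations)
  attempt <- 0L
  repeat {
    fit <- gibbs_run(spec, w, chains, it, seed = seed + attempt,
                     prior_upper = prior_upper, fixed = fixed,
                     init_jitter = init_jitter)
    rh <- rhat(fit)
    monitored <- !fit$param_map$fixed
    rmax <- suppressWarnings(max(rh[monitored], na.rm = TRUE))
    if (is.finite(rmax) && rmax <= rhat_threshold) {
      fit$converged <- TRUE
      break
    }
    if (attempt >= max_doublings) {
      warning("chains not converged after ", it, " iterations (max R-hat = ",
              signif(rmax, 4), "); result flagged")
      fit$converged <- FALSE
      break
    }
    attempt <- attempt + 1L
    it <- it * 2L
  }
  fit$rhat <- rh
  fit$rhat_max <- rmax
  fit$weighting <- weighting
  fit
}

# one complete multi-chain Gibbs run; returns an apc_draws object
gibbs_run <- function(spec, w, chains, iterations, seed, prior_upper,
                      fixed, init_jitter) {
  set.seed(as.integer(seed))
  q <- spec$q
  y <- spec$y
  X <- spec$X
  XtW <- t(X * w)
  XtWX <- XtW %*% X
  XtWy <- drop(XtW %*% y)
  Kb <- penalty_mats(spec)
  eff <- spec$effects
  n_obs <- spec$n_obs

  fix_sigma <- !is.null(fixed$sigma)
  fix_tau <- !is.null(fixed$tau)
  if (fix_tau) fixed$tau <- expand_tau(fixed$tau, eff)

  # parameter layout: full effect vectors (constrained zeros kept), then
  # sigma and one tau per effect
  pm <- do.call(rbind, lapply(eff, function(e) {
    b <- spec$blocks[[e]]
    data.frame(param = paste0(e, "_", b$levels), effect = e,
               level = b$levels,
               free = seq_along(b$levels) %in% b$free,
               fixed = !(seq_along(b$levels) %in% b$free))
  }))
  hyp <- data.frame(param = c("sigma", paste0("tau_", eff)),
                    effect = c("sigma", rep("tau", length(eff))),
                    level = NA_integer_,
                    free = TRUE,
                    fixed = c(fix_sigma, rep(fix_tau, length(eff))))
  pm <- rbind(pm, hyp)
  npar <- nrow(pm)
  theta_cols <- which(pm$effect %in% eff)
  # map free beta coordinates into the stored parameter columns
  beta_to_par <- unlist(lapply(eff, function(e) {
    b <- spec$blocks[[e]]
    which(pm$effect == e)[b$free]
  }), use.names = FALSE)
  sigma_col <- which(pm$param == "sigma")
  tau_col <- stats::setNames(match(paste0("tau_", eff), pm$param), eff)

  burn <- iterations %/% 2L
  kept <- iterations - burn
  draws <- array(NA_real_, c(kept, npar, chains),
                 dimnames = list(NULL, pm$param, paste0("chain", seq_len(chains))))

  # dispersed starts around the penalised mode at unit hyperparameters
  tau0 <- if (fix_tau) fixed$tau else stats::setNames(rep(1, length(eff)), eff)
  sigma0 <- if (fix_sigma) fixed$sigma else {
    pen0 <- penalized_solve(XtWX, XtWy, Kb, tau0, 1)
    max(sqrt(sum(w * (y - drop(X %*% pen0))^2) / max(1, n_obs)), 1e-3)
  }
  beta_mode <- penalized_solve(XtWX, XtWy, Kb, tau0, sigma0)

  for (ch in seq_len(chains)) {
    beta <- beta_mode + stats::rnorm(q, 0, init_jitter * ch)
    sigma <- if (fix_sigma) fixed$sigma else
      min(max(sigma0 * exp(stats::runif(1, -1, 1) * 0.5 * ch / chains), 1e-3),
          prior_upper * 0.9)
    tau <- if (fix_tau) fixed$tau else
      stats::setNames(pmin(exp(stats::runif(length(eff), -1, 1)), prior_upper * 0.9), eff)

    for (i in seq_len(iterations)) {
      # (i) joint Gaussian draw of the effect coefficients
      K <- kb_sum(Kb, tau, eff)
      Q <- XtWX / sigma^2 + K
      R <- chol(Q)
      mu <- backsolve(R, forwardsolve(t(R), XtWy / sigma^2))
      beta <- drop(mu + backsolve(R, stats::rnorm(q)))
      resid2 <- sum(w * (y - drop(X %*% beta))^2)

      # (ii) slice updates of sigma and the RW2 innovation SDs
      if (!fix_sigma)
        sigma <- slice1(sigma,
                        function(s) -n_obs * log(s) - resid2 / (2 * s^2),
                        w = sigma / 2 + 0.05, lower = 1e-6,
                        upper = prior_upper)
      if (!fix_tau) {
        for (e in eff) {
          b <- spec$blocks[[e]]
          m <- nrow(b$D)
          if (m == 0L) { tau[e] <- stats::runif(1, 0, prior_upper); next }
          th <- numeric(length(b$levels))
          th[b$free] <- beta[b$cols]
          d2 <- sum((b$D %*% th)^2)
          tau[e] <- slice1(tau[[e]],
                           function(t) -m * log(t) - d2 / (2 * t^2),
                           w = tau[[e]] / 2 + 0.05, lower = 1e-6,
                           upper = prior_upper)
        }
      }

      if (i > burn) {
        draws[i - burn, beta_to_par, ch] <- beta
        draws[i - burn, sigma_col, ch] <- sigma
        draws[i - burn, tau_col, ch] <- tau
      }
    }
  }
  # constrained positions are exactly zero in every draw
  draws[, theta_cols[pm$fixed[theta_cols]], ] <- 0

  structure(list(draws = draws, param_map = pm, design = spec$design,
                 effects = eff, table = spec$table, chains = chains,
                 iterations = iterations, burn = burn, seed = seed,
                 prior_upper = prior_upper,
                 fixed = fixed, converged = NA),
            class = "apc_draws")
}

kb_sum <- function(Kb, tau, eff) {
  K <- Kb[[eff[1]]] / tau[[eff[1]]]^2
  for (e in eff[-1]) K <- K + Kb[[e]] / tau[[e]]^2
  K
}

penalized_solve <- function(XtWX, XtWy, Kb, tau, sigma) {
  eff <- names(Kb)
  drop(solve(XtWX / sigma^2 + kb_sum(Kb, tau, eff), XtWy / sigma^2))
}

# univariate slice sampler (stepping out + shrinkage), bounded support
slice1 <- function(x0, logf, w, lower = 0, upper = Inf, max_steps = 30L) {
  ly <- logf(x0) - stats::rexp(1)
  u <- stats::runif(1) * w
  L <- x0 - u
  R <- x0 + (w - u)
  j <- floor(stats::runif(1) * max_steps)
  k <- max_steps - 1L - j
  while (j > 0 && L > lower && logf(L) > ly) { L <- L - w; j <- j - 1L }
  while (k > 0 && R < upper && logf(R) > ly) { R <- R + w; k <- k - 1L }
  L <- max(L, lower)
  R <- min(R, upper)
  repeat {
    x1 <- stats::runif(1, L, R)
    if (logf(x1) >= ly) return(x1)
    if (x1 < x0) L <- x1 else R <- x1
  }
}

#' @export
print.apc_draws <- function(x, ...) {
  cat("Bayesian APC fit (", paste(x$effects, collapse = "+"), " model): ",
      x$chains, " chains x ", x$iterations, " iterations (burn-in ",
      x$burn, ")\n", sep = "")
  if (!is.na(x$converged))
    cat("converged:", x$converged,
        if (!is.null(x$rhat_max)) paste0("(max R-hat ", signif(x$rhat_max, 4), ")"),
        "\n")
  invisible(x)
}
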