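#' Split-chain R-hat convergence diagnostic
#'
#' Potential scale reduction factor computed after splitting each chain in
#' half, so within-chain trends register as apparent non-convergence. For a
#' parameter with zero within-chain variance the statistic is defined as 1
#' when all chains agree (with a warning for monitored parameters) and `Inf`
#' when chains sit at different constants.
#'
#' @param x an `apc_draws` object, or a 3-d array `[iteration, parameter,
#'   chain]`.
#' @param rank_normalize if `TRUE`, compute R-hat on rank-normalised draws.
#' @return named numeric vector of R-hat values, one per parameter.
#' @export
rhat <- function(x, rank_normalize = FALSE) {
  arr <- if (inherits(x, "apc_draws")) x$draws else x
  stopifnot(length(dim(arr)) == 3L)
  if (dim(arr)[3] < 2L) stop("R-hat needs at least 2 chains")
  if (dim(arr)[1] < 4L) stop("R-hat needs at least 4 retained draws per chain")
  monitored <- if (inherits(x, "apc_draws")) !x$param_map$fixed else
    rep(TRUE, dim(arr)[2])
  n2 <- dim(arr)[1] %/% 2L
  out <- numeric(dim(arr)[2])
  warned <- FALSE
  for (p in seq_len(dim(arr)[2])) {
    # split every chain in half -> 2m sequences of length n2
    segs <- do.call(cbind, lapply(seq_len(dim(arr)[3]), function(ch)
      cbind(arr[seq_len(n2), p, ch], arr[n2 + seq_len(n2), p, ch])))
    if (rank_normalize) {
      r <- rank(segs, ties.method = "average")
      segs <- matrix(stats::qnorm((r - 3 / 8) / (length(segs) + 1 / 4)),
                     nrow = n2)
    }
    W <- mean(apply(segs, 2, stats::var))
    B <- n2 * stats::var(colMeans(segs))
    if (W <= .Machine$double.eps * max(1, abs(mean(segs)))^2) {
      out[p] <- if (B <= .Machine$double.eps) 1 else Inf
      if (monitored[p] && !warned && is.finite(out[p])) {
        warning("zero within-chain variance for parameter ", p,
                "; R-hat set to 1")
        warned <- TRUE
      }
    } else {
      out[p] <- sqrt(((n2 - 1) / n2 * W + B / n2) / W)
    }
  }
  names(out) <- if (inherits(x, "apc_draws")) x$param_map$param else
    dimnames(arr)[[2]]
  out
}

# flatten chains into one draws matrix [total kept draws, parameter]
draws_matrix <- function(fit) {
  arr <- fit$draws
  d <- dim(arr)
  m <- matrix(aperm(arr, c(1, 3, 2)), d[1] * d[3], d[2])
  colnames(m) <- fit$param_map$param
  m
}

#' Posterior summary of an APC fit
#'
#' Posterior mean, central 95% credible interval and split-chain R-hat per
#' stored parameter (full effect vectors including the exact-zero reference
#' positions, plus `sigma` and the RW2 innovation SDs).
#'
#' @param fit an `apc_draws` object.
#' @param prob credible level (default 0.95, central interval).
#' @return data.frame: `param`, `effect`, `level`, `mean`, `lower`, `upper`,
#'   `rhat`.
#' @export
summarize_draws <- function(fit, prob = 0.95) {
  stopifnot(inherits(fit, "apc_draws"), prob > 0, prob < 1)
  m <- draws_matrix(fit)
  a <- (1 - prob) / 2
  qs <- apply(m, 2, stats::quantile, probs = c(a, 1 - a), names = FALSE)
  rh <- if (!is.null(fit$rhat)) fit$rhat else suppressWarnings(rhat(fit))
  data.frame(
    param = fit$param_map$param,
    effect = fit$param_map$effect,
    level = fit$param_map$level,
    mean = colMeans(m),
    lower = qs[1, ],
    upper = qs[2, ],
    rhat = unname(rh),
    row.names = NULL
  )
}

#' Posterior draws of one effect vector
#'
#' @param fit an `apc_draws` object.
#' @param effect `"age"`, `"period"` or `"cohort"`.
#' @return matrix `[draw, level]` with level years as column names.
#' @export
effect_draws <- function(fit, effect = c("age", "period", "cohort")) {
  effect <- match.arg(effect)
  if (!effect %in% fit$effects)
    stop("effect '", effect, "' is not part of this fit")
  m <- draws_matrix(fit)
  sel <- fit$param_map$effect == effect
  out <- m[, sel, drop = FALSE]
  colnames(out) <- fit$param_map$level[sel]
  out
}

# per-draw fitted cell means for the fit's own stratum table (or any table
# on the same design); returns matrix [draw, cell]
fitted_cell_draws <- function(fit, table = fit$table) {
  m <- draws_matrix(fit)
  out <- matrix(0, nrow(m), nrow(table))
  for (e in fit$effects) {
    lev <- fit$param_map$level[fit$param_map$effect == e]
    obs <- switch(e, age = table$age, period = table$period,
                  cohort = table$period - table$age)
    cols <- which(fit$param_map$effect == e)[match(obs, lev)]
    if (anyNA(cols)) stop("table contains levels outside the fitted grids")
    out <- out + m[, cols, drop = FALSE]
  }
  out
}

#' Deviance information criterion of an APC fit
#'
#' The deviance is minus twice the normal log-likelihood of the cell means,
#' `D(theta) = -2 sum log N(y_i; mu_i, sigma^2 / w_i)`. `Dbar` is its
#' posterior mean, `pD = Dbar - D(posterior mean of all parameters)` the
#' effective parameter count (Spiegelhalter plug-in), and
#' `DIC = Dbar + pD`. Smaller DIC indicates better expected predictive fit.
#'
#' @param fit an `apc_draws` object.
#' @return list with `Dbar`, `pD`, `DIC`.
#' @export
dic <- function(fit) {
  stopifnot(inherits(fit, "apc_draws"))
  tab <- fit$table
  w <- obs_weights(tab, fit$weighting %||% "1")
  y <- tab$mean
  mu <- fitted_cell_draws(fit)
  sig <- draws_matrix(fit)[, "sigma"]
  # D per draw, vectorised over cells
  sse <- rowSums(sweep((mu - rep(y, each = nrow(mu)))^2, 2, w, `*`))
  n <- length(y)
  Dvec <- n * log(2 * pi) + n * 2 * log(sig) - sum(log(w)) + sse / sig^2
  Dbar <- mean(Dvec)
  mu_bar <- colMeans(mu)
  sig_bar <- mean(sig)
  Dhat <- n * log(2 * pi) + n * 2 * log(sig_bar) - sum(log(w)) +
    sum(w * (y - mu_bar)^2) / sig_bar^2
  pD <- Dbar - Dhat
  list(Dbar = Dbar, pD = pD, DIC = Dbar + pD)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Compare APC sub-models by DIC
#'
#' Fits each requested sub-model (`"A"`, `"AP"`, `"AC"`, `"APC"`; blocks and
#' their corner constraints dropped together) to the same stratum table and
#' tabulates Dbar, pD and DIC. A smaller DIC implies a better fit; the
#' minimum-DIC row is flagged.
#'
#' @param table stratum table (one sex).
#' @param design an [build_design()] object.
#' @param models character subset of `c("A", "AP", "AC", "APC")`.
#' @param ... passed to [fit_apc()] (chains, iterations, seed, ...).
#' @return data.frame: `model`, `Dbar`, `pD`, `DIC`, `best`.
#' @export
compare_models <- function(table, design,
                           models = c("A", "AP", "AC", "APC"), ...) {
  models <- match.arg(models, c("A", "AP", "AC", "APC"), several.ok = TRUE)
  eff_of <- list(A = "age", AP = c("age", "period"), AC = c("age", "cohort"),
                 APC = c("age", "period", "cohort"))
  rows <- lapply(models, function(mn) {
    fit <- fit_apc(table, design, effects = eff_of[[mn]], ...)
    d <- dic(fit)
    data.frame(model = mn, Dbar = d$Dbar, pD = d$pD, DIC = d$DIC)
  })
  out <- do.call(rbind, rows)
  out$best <- out$DIC == min(out$DIC)
  out
}
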