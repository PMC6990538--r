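#' Curvature (second-difference) of an effect series
#'
#' The curvature component at an interior position j is
#' `theta[j+1] - 2 theta[j] + theta[j-1]`. Because adding any straight line
#' to an effect vector leaves its second differences unchanged, curvature is
#' exactly invariant to the arbitrary linear trend that the APC
#' identification problem cannot pin down -- which is why inflection points,
#' not slopes, are the interpretable features of the fitted effects.
#'
#' @param x a numeric series, or a matrix of posterior draws `[draw, level]`
#'   (e.g. from [effect_draws()]), with level years as names/colnames.
#' @param prob credible level for the draw-wise interval (default 0.95).
#' @return object of class `apc_curvature`: data.frame with `position`
#'   (the interior level), `mean`, and for draw input `lower`, `upper`.
#' @export
curvature <- function(x, prob = 0.95) {
  if (is.matrix(x)) {
    if (ncol(x) < 3L) stop("curvature needs a series of length >= 3")
    d2 <- x[, -(1:2), drop = FALSE] - 2 * x[, -c(1, ncol(x)), drop = FALSE] +
      x[, -((ncol(x) - 1):ncol(x)), drop = FALSE]
    pos <- colnames(x)[-c(1, ncol(x))]
    a <- (1 - prob) / 2
    qs <- apply(d2, 2, stats::quantile, probs = c(a, 1 - a), names = FALSE)
    out <- data.frame(position = pos_num(pos, ncol(x) - 2L),
                      mean = colMeans(d2), lower = qs[1, ], upper = qs[2, ],
                      row.names = NULL)
    structure(list(series = out, draws = d2, prob = prob,
                   from_draws = TRUE), class = "apc_curvature")
  } else {
    n <- length(x)
    if (n < 3L) stop("curvature needs a series of length >= 3")
    d2 <- x[-(1:2)] - 2 * x[-c(1, n)] + x[-((n - 1):n)]
    out <- data.frame(position = pos_num(names(x)[-c(1, n)], n - 2L),
                      mean = unname(d2), row.names = NULL)
    structure(list(series = out, draws = NULL, prob = prob,
                   from_draws = FALSE), class = "apc_curvature")
  }
}

pos_num <- function(nm, len) {
  if (is.null(nm)) return(seq_len(len) + 1L)
  v <- suppressWarnings(as.numeric(nm))
  if (anyNA(v)) nm else v
}

#' Flag inflection points from a curvature series
#'
#' A position is flagged when its curvature credible interval excludes zero
#' and the absolute posterior mean curvature reaches `min_magnitude`;
#' positive curvature is tagged as an upward inflection, negative as
#' downward. (Visual inspection of curvature plots is the field's usual
#' practice; this rule makes it reproducible.)
#'
#' @param cv an [curvature()] result computed from posterior draws.
#' @param credible_level interval level used for the exclusion rule.
#' @param min_magnitude minimum |posterior mean| curvature (outcome units).
#' @return data.frame: `position`, `mean`, `lower`, `upper`, `direction`.
#' @export
inflection_points <- function(cv, credible_level = 0.95, min_magnitude = 0) {
  stopifnot(inherits(cv, "apc_curvature"))
  if (!cv$from_draws)
    stop("inflection flagging needs a curvature computed from draws")
  a <- (1 - credible_level) / 2
  qs <- apply(cv$draws, 2, stats::quantile, probs = c(a, 1 - a), names = FALSE)
  s <- cv$series
  keep <- (qs[1, ] > 0 | qs[2, ] < 0) & abs(s$mean) >= min_magnitude
  out <- data.frame(position = s$position[keep], mean = s$mean[keep],
                    lower = qs[1, keep], upper = qs[2, keep],
                    direction = ifelse(s$mean[keep] > 0, "upward", "downward"),
                    row.names = NULL)
  out
}

#' Joinpoint (piecewise-linear changepoint) regression
#'
#' Fits continuous piecewise-linear trends with 0..`max_joinpoints`
#' breakpoints placed at observed years, by exhaustive search over all
#' admissible placements with ordinary least squares per candidate, and
#' selects the model minimising a modified Bayesian information criterion
#' `MBIC(k) = n log(SSE_k / n) + (2k + 2) log(n)` (each joinpoint costs a
#' location and a slope change; +2 for the base intercept and slope). Ties
#' are broken toward fewer joinpoints, then earliest placements. Breakpoints
#' are restricted to interior years with at least `min_segment` observations
#' strictly on each side and strictly between consecutive breakpoints.
#'
#' @param year numeric vector of years (strictly increasing).
#' @param value numeric series (e.g. a yearly mean outcome).
#' @param max_joinpoints maximum number of breakpoints searched.
#' @param min_segment minimum observations per open segment (default 2).
#' @return object of class `apc_joinpoint`: `joinpoints` (years),
#'   `slopes` (per segment, outcome units per year), `fitted`, `sse`,
#'   `mbic`, and a `candidates` table with the best fit for each k.
#' @export
joinpoint_fit <- function(year, value, max_joinpoints = 3L, min_segment = 2L) {
  stopifnot(length(year) == length(value), !is.unsorted(year, strictly = TRUE))
  n <- length(year)
  max_joinpoints <- as.integer(max_joinpoints)
  k_feasible <- function(k) n >= (k + 1L) * min_segment + k
  if (!k_feasible(max_joinpoints))
    stop("series too short: ", n, " points cannot support ", max_joinpoints,
         " joinpoint(s) with ", min_segment, " points per segment (need ",
         (max_joinpoints + 1L) * min_segment + max_joinpoints, ")")

  fit_one <- function(jp) {
    X <- cbind(1, year)
    for (j in jp) X <- cbind(X, pmax(year - j, 0))
    f <- stats::lm.fit(X, value)
    sse <- sum(f$residuals^2)
    list(sse = sse, coef = f$coefficients, fitted = f$fitted.values)
  }

  # admissible placements: interior years with >= min_segment points strictly
  # outside / between breakpoints
  idx_all <- seq_len(n)
  placements <- function(k) {
    if (k == 0L) return(list(integer(0)))
    cand <- idx_all[idx_all > min_segment & idx_all <= n - min_segment]
    cmb <- utils::combn(cand, k, simplify = FALSE)
    Filter(function(ii) k == 1L || all(diff(ii) > min_segment), cmb)
  }

  best <- NULL
  cand_rows <- list()
  for (k in 0:max_joinpoints) {
    if (!k_feasible(k)) break
    best_k <- NULL
    for (ii in placements(k)) {
      f <- fit_one(year[ii])
      if (is.null(best_k) || f$sse < best_k$sse - 1e-12)
        best_k <- c(f, list(jp = year[ii], k = k))
    }
    if (is.null(best_k)) next
    mbic <- n * log(max(best_k$sse, 1e-12) / n) + (2 * k + 2) * log(n)
    cand_rows[[length(cand_rows) + 1L]] <-
      data.frame(k = k, joinpoints = paste(best_k$jp, collapse = ","),
                 sse = best_k$sse, mbic = mbic)
    if (is.null(best) || mbic < best$mbic - 1e-12)
      best <- c(best_k, list(mbic = mbic))
  }
  slopes <- cumsum(best$coef[-1])
  structure(list(
    joinpoints = best$jp, k = best$k, slopes = unname(slopes),
    fitted = unname(best$fitted), sse = best$sse, mbic = best$mbic,
    candidates = do.call(rbind, cand_rows), year = year, value = value
  ), class = "apc_joinpoint")
}

#' @export
print.apc_joinpoint <- function(x, ...) {
  cat("Joinpoint fit:", x$k, "joinpoint(s)",
      if (x$k > 0) paste0("at ", paste(x$joinpoints, collapse = ", ")),
      "\n  segment slopes:", paste(signif(x$slopes, 4), collapse = ", "),
      "\n  SSE:", signif(x$sse, 6), " MBIC:", signif(x$mbic, 6), "\n")
  invisible(x)
}
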