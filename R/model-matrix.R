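# Internal model specification: constrained design matrix, parameter map and
# RW2 penalty blocks for a stratum table on an APC design.
#
# Identification follows the corner-constraint convention: the second and
# penultimate period effects and the central cohort effect are fixed at zero;
# age effects are unconstrained (absolute outcome level). Sub-models are
# obtained by dropping whole effect blocks together with their constraints.

effect_levels <- function(design, effect) {
  switch(effect,
         age = design$ages,
         period = design$periods,
         cohort = design$cohorts,
         stop("unknown effect: ", effect))
}

constrained_positions <- function(design, effect) {
  switch(effect,
         age = integer(0),
         period = unique(c(design$ref_period_low, design$ref_period_high)),
         cohort = design$ref_cohort)
}

# second-difference matrix for a length-L effect vector ((L-2) x L)
second_diff_matrix <- function(L) {
  if (L < 3L) return(matrix(0, 0L, L))
  D <- matrix(0, L - 2L, L)
  for (j in seq_len(L - 2L)) D[j, j:(j + 2L)] <- c(1, -2, 1)
  D
}

# effects: character subset of c("age", "period", "cohort"), in that order
apc_model_spec <- function(design, table, effects = c("age", "period", "cohort"),
                           constrain = TRUE, check_rank = constrain) {
  stopifnot(inherits(design, "apc_design"))
  effects <- match.arg(effects, c("age", "period", "cohort"),
                       several.ok = TRUE)
  if (!all(table$age %in% design$ages) || !all(table$period %in% design$periods))
    stop("stratum table contains cells off the design grids")
  if (length(unique(table$sex)) > 1L)
    stop("fit one sex at a time (analyses are sex-stratified)")

  n <- nrow(table)
  blocks <- list()
  cols <- list()
  par_names <- character(0)
  map <- list()
  col0 <- 0L
  for (e in effects) {
    lev <- effect_levels(design, e)
    L <- length(lev)
    con <- if (constrain) constrained_positions(design, e) else integer(0)
    free <- setdiff(seq_len(L), con)
    obs_lev <- switch(e, age = table$age, period = table$period,
                      cohort = table$period - table$age)
    pos <- match(obs_lev, lev)
    # indicator columns for free positions only (constrained levels are 0)
    Xe <- matrix(0, n, length(free))
    hit <- match(pos, free)
    ok <- !is.na(hit)
    Xe[cbind(which(ok), hit[ok])] <- 1
    D <- second_diff_matrix(L)
    Pfull <- crossprod(D)
    blocks[[e]] <- list(levels = lev, free = free, constrained = con,
                        cols = col0 + seq_along(free),
                        D = D, K_free = Pfull[free, free, drop = FALSE])
    cols[[e]] <- Xe
    if (length(free) > 0L)
      par_names <- c(par_names, paste0(e, "_", lev[free]))
    col0 <- col0 + length(free)
  }
  X <- do.call(cbind, cols)
  colnames(X) <- par_names
  q <- ncol(X)
  r <- qr(X)$rank
  if (check_rank && r < q)
    stop("design matrix is rank deficient (rank ", r, " < ", q,
         " columns): the occupied cells do not identify the constrained ",
         "effects")
  list(design = design, effects = effects, blocks = blocks, X = X, q = q,
       y = table$mean, n_obs = n, table = table)
}

obs_weights <- function(table, weighting = c("1", "n")) {
  weighting <- match.arg(weighting)
  if (weighting == "1") rep(1, nrow(table)) else {
    if (anyNA(table$n)) stop("weighting = 'n' needs cell counts in the table")
    as.numeric(table$n)
  }
}

# embed per-effect free-coordinate penalty blocks into q x q matrices
penalty_mats <- function(spec) {
  lapply(spec$blocks, function(b) {
    K <- matrix(0, spec$q, spec$q)
    if (length(b$cols) > 0 && nrow(b$K_free) > 0)
      K[b$cols, b$cols] <- b$K_free
    K
  })
}

# expand free coefficients to the full effect vector (zeros at constraints)
full_theta <- function(spec, beta) {
  out <- lapply(spec$blocks, function(b) {
    th <- numeric(length(b$levels))
    th[b$free] <- beta[b$cols]
    stats::setNames(th, b$levels)
  })
  names(out) <- names(spec$blocks)
  out
}

#' Constrained APC design matrix
#'
#' One row per stratum; indicator columns for all ages, the non-reference
#' periods and the non-reference cohorts. The matrix is checked for full
#' column rank `A + (P-2) + (C-1)`; occupancy patterns that fail to identify
#' the constrained parameterisation raise an error.
#'
#' @param design an [build_design()] object.
#' @param table a stratum table (one sex).
#' @param effects which effect blocks to include (sub-models drop blocks and
#'   their constraints).
#' @param constrain set `FALSE` to build the unconstrained (rank-deficient)
#'   indicator matrix, e.g. to inspect the identifiability deficit.
#' @return list with `X` (the matrix, named columns), `column_map`
#'   (data.frame: column, effect, level) and `rank`.
#' @export
build_design_matrix <- function(design, table,
                                effects = c("age", "period", "cohort"),
                                constrain = TRUE) {
  spec <- apc_model_spec(design, table, effects, constrain = constrain)
  X <- spec$X
  cm <- do.call(rbind, lapply(names(spec$blocks), function(e) {
    b <- spec$blocks[[e]]
    if (length(b$cols) == 0L) return(NULL)
    data.frame(column = b$cols, effect = e, level = b$levels[b$free])
  }))
  list(X = X, column_map = cm, rank = qr(X)$rank)
}
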