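#' Construct an age-period-cohort design
#'
#' Builds the grids of single-year ages, examination periods and the induced
#' birth-cohort indices `k = period - age`, together with the reference
#' (corner-constraint) positions used for identification: the second and the
#' penultimate period, and the central birth cohort. Age effects carry no
#' constraint and are estimated on the absolute outcome scale.
#'
#' With `A` ages and `P` periods the design spans `C = A + P - 1` cohorts,
#' running from `period_min - age_max` to `period_max - age_min`.
#'
#' @param age_min,age_max integer years, inclusive age range.
#' @param period_min,period_max integer calendar years, inclusive.
#' @return An object of class `apc_design`: a list with `ages`, `periods`,
#'   `cohorts` (integer vectors), `ref_period_low`, `ref_period_high`,
#'   `ref_cohort` (1-based positions into `periods` / `cohorts`), and the
#'   dimensions `A`, `P`, `C`.
#' @examples
#' d <- build_design(9, 18, 1999, 2014)  # 10 ages, 16 periods, 25 cohorts
#' d$C                                   # 25
#' @export
build_design <- function(age_min, age_max, period_min, period_max) {
  if (age_min > age_max)
    stop("invalid age range: age_min (", age_min, ") > age_max (", age_max, ")")
  if (period_min > period_max)
    stop("invalid period range: period_min (", period_min,
         ") > period_max (", period_max, ")")
  ages    <- seq.int(age_min, age_max)
  periods <- seq.int(period_min, period_max)
  cohorts <- seq.int(period_min - age_max, period_max - age_min)
  P <- length(periods)
  C <- length(cohorts)
  d <- list(
    ages = ages, periods = periods, cohorts = cohorts,
    A = length(ages), P = P, C = C,
    # second / penultimate period; for P < 4 the positions degenerate but
    # stay in range so tiny toy designs remain constructible
    ref_period_low  = min(2L, P),
    ref_period_high = max(P - 1L, 1L),
    ref_cohort      = as.integer(ceiling(C / 2))
  )
  class(d) <- "apc_design"
  d
}

#' @export
print.apc_design <- function(x, ...) {
  cat("APC design: ", x$A, " ages (", min(x$ages), "-", max(x$ages), "), ",
      x$P, " periods (", min(x$periods), "-", max(x$periods), "), ",
      x$C, " cohorts (", min(x$cohorts), "-", max(x$cohorts), ")\n", sep = "")
  cat("reference periods: ", x$periods[x$ref_period_low], ", ",
      x$periods[x$ref_period_high],
      "; reference cohort: ", x$cohorts[x$ref_cohort],
      " (", cohort_label(0, x$cohorts[x$ref_cohort]), ")\n", sep = "")
  invisible(x)
}

#' Two-year birth-cohort label for an (age, period) cell
#'
#' Children of the same whole-year age examined in the same school year can be
#' born in either of two adjacent calendar years, so each cohort index
#' `k = period - age` is displayed as the two-year label `"(k-1)-k"`.
#'
#' @param age age in whole years.
#' @param period examination calendar year.
#' @return character label, e.g. `cohort_label(18, 1999)` is `"1980-1981"`.
#' @export
cohort_label <- function(age, period) {
  k <- period - age
  paste0(k - 1L, "-", k)
}

#' Design bookkeeping summary
#'
#' Number of strata (cells), number of regression parameters, and the
#' per-stratum average count, truncated toward zero.
#'
#' @param design an [build_design()] object.
#' @param total_n total record count across all strata (one sex).
#' @return list with `strata` (= A*P), `parameters` (= A+P+C) and
#'   `avg_per_stratum` (= floor(total_n / strata)).
#' @export
design_summary <- function(design, total_n) {
  stopifnot(inherits(design, "apc_design"), total_n >= 0)
  strata <- design$A * design$P
  list(
    strata = strata,
    parameters = design$A + design$P + design$C,
    avg_per_stratum = as.integer(total_n %/% strata)
  )
}
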