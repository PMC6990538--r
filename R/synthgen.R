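#' Define the generating truth of a synthetic population
#'
#' An `apc_truth` bundles the three additive effect curves and the residual
#' standard deviation used to simulate individual records: the outcome of a
#' child aged `a`, examined in year `p` (hence born around `k = p - a`), is
#' `age_curve[a] + period_curve[p] + cohort_curve[k] + Normal(0, residual_sd)`.
#' The age curve is on the absolute outcome scale (e.g. mmHg); period and
#' cohort curves are additive offsets around it.
#'
#' @param age_curve named numeric vector, names = ages in years.
#' @param period_curve named numeric vector, names = calendar years.
#' @param cohort_curve named numeric vector, names = birth years (cohort
#'   indices `period - age`).
#' @param residual_sd positive residual standard deviation, outcome units.
#' @return object of class `apc_truth`.
#' @seealso [default_truth()] for curves shaped like the observed school
#'   surveillance series.
#' @export
apc_truth <- function(age_curve, period_curve, cohort_curve, residual_sd) {
  stopifnot(is.numeric(age_curve), is.numeric(period_curve),
            is.numeric(cohort_curve))
  if (is.null(names(age_curve)) || is.null(names(period_curve)) ||
      is.null(names(cohort_curve)))
    stop("truth curves must be named by their year grids")
  if (!is.numeric(residual_sd) || length(residual_sd) != 1L || residual_sd < 0)
    stop("residual_sd must be a single non-negative number")
  structure(list(age_curve = age_curve, period_curve = period_curve,
                 cohort_curve = cohort_curve, residual_sd = residual_sd),
            class = "apc_truth")
}

#' Default truth curves for a design
#'
#' Produces smooth effect curves qualitatively shaped like the observed
#' school-surveillance trends for the chosen outcome: an age curve rising
#' through puberty with an upward inflection near 10 years (boys) or 9 years
#' (girls), a V-shaped period curve with its minimum near 2005, and a cohort
#' curve with inflections near the 1993 and 1998 birth cohorts. The curves are
#' a configurable simulation default, not estimates of any real series.
#'
#' @param design an [build_design()] object.
#' @param outcome_kind one of `"sbp"`, `"dbp"`, `"bmi"` (sets the base level
#'   and effect scale).
#' @param sex `"male"` or `"female"` (shifts the pubertal inflection age).
#' @param residual_sd residual SD of individual measurements; defaults to
#'   10 mmHg for blood pressure and 2.5 kg/m2 for BMI.
#' @return an [apc_truth()] object covering the design's grids.
#' @export
default_truth <- function(design, outcome_kind = c("sbp", "dbp", "bmi"),
                          sex = c("male", "female"), residual_sd = NULL) {
  outcome_kind <- match.arg(outcome_kind)
  sex <- match.arg(sex)
  stopifnot(inherits(design, "apc_design"))
  base <- switch(outcome_kind, sbp = 100, dbp = 58, bmi = 17)
  slope <- switch(outcome_kind, sbp = 1.2, dbp = 0.5, bmi = 0.35)
  inflect_age <- if (sex == "male") 10 else 9
  a <- design$ages
  # piecewise-quadratic rise: gentle before the pubertal inflection, steeper after
  age_curve <- base + slope * (a - min(a)) +
    0.4 * slope * pmax(a - inflect_age, 0)^2 / max(1, diff(range(a)))
  # V-shaped period effect, minimum at 2005 (clamped into the grid)
  p <- design$periods
  vertex <- min(max(2005, min(p)), max(p))
  period_curve <- 0.12 * abs(p - vertex) - 0.12 * mean(abs(p - vertex))
  # cohort effect: rise to the 1993 cohort, fall after 1998
  k <- design$cohorts
  cohort_curve <- 0.08 * (pmin(k, 1993) - min(k)) - 0.10 * pmax(k - 1998, 0)
  cohort_curve <- cohort_curve - mean(cohort_curve)
  if (is.null(residual_sd))
    residual_sd <- if (outcome_kind == "bmi") 2.5 else 10
  apc_truth(stats::setNames(age_curve, a), stats::setNames(period_curve, p),
            stats::setNames(cohort_curve, k), residual_sd)
}

# look up curve values, erroring with the offending grid point
curve_at <- function(curve, at, what) {
  v <- curve[as.character(at)]
  if (anyNA(v))
    stop("truth ", what, " is missing grid point(s): ",
         paste(at[is.na(v)], collapse = ", "))
  unname(v)
}

check_truth_covers <- function(truth, design) {
  curve_at(truth$age_curve, design$ages, "age_curve")
  curve_at(truth$period_curve, design$periods, "period_curve")
  curve_at(truth$cohort_curve, design$cohorts, "cohort_curve")
  invisible(TRUE)
}

#' Simulate a synthetic school-health population
#'
#' Each synthetic child is assigned a birth year and advances along its cohort
#' diagonal: annual check-ups at consecutive (age, period) pairs with
#' `period - age` constant, mirroring yearly school health assessments. Visits
#' falling outside the design's age or period range are not generated, so a
#' child has *up to* `visits_per_child` records. Outcomes are independent
#' normal draws around the additive cell mean (repeat visits of one child are
#' not given extra within-child correlation; downstream analysis keeps a
#' single randomly chosen visit per child anyway).
#'
#' @param truth an [apc_truth()] covering the design.
#' @param design an [build_design()] object.
#' @param visits_per_child maximum number of annual visits per child.
#' @param n_children_per_birth_year children simulated per birth year with at
#'   least one in-design visit.
#' @param seed integer RNG seed; identical seeds give identical tables.
#' @param sex record label, `"male"` or `"female"`.
#' @param outcome_kind record label, `"sbp"`, `"dbp"` or `"bmi"`.
#' @return data.frame of individual records with columns `child_id`, `sex`,
#'   `age`, `period`, `outcome_kind`, `outcome`.
#' @export
generate_population <- function(truth, design, visits_per_child = 1L,
                                n_children_per_birth_year = 100L,
                                seed = 1L, sex = "male",
                                outcome_kind = "sbp") {
  stopifnot(inherits(truth, "apc_truth"), inherits(design, "apc_design"),
            visits_per_child >= 1, n_children_per_birth_year >= 1)
  if (missing(seed) || is.null(seed)) stop("a seed is required")
  check_truth_covers(truth, design)
  set.seed(as.integer(seed))

  out <- vector("list", design$C)
  id0 <- 0L
  for (ci in seq_along(design$cohorts)) {
    b <- design$cohorts[ci]
    # ages at which this birth year can be observed inside the design window
    valid_ages <- design$ages[(design$ages + b) >= min(design$periods) &
                              (design$ages + b) <= max(design$periods)]
    if (length(valid_ages) == 0L) next
    n <- n_children_per_birth_year
    # each child is followed for consecutive years; the follow-up window is
    # placed uniformly at random inside the observable part of the diagonal
    # (shorter diagonals truncate the window)
    v <- min(visits_per_child, length(valid_ages))
    si <- sample.int(length(valid_ages) - v + 1L, n, replace = TRUE)
    rows <- lapply(seq_len(n), function(j) {
      a <- valid_ages[si[j]:(si[j] + v - 1L)]
      data.frame(child_id = sprintf("c%d_%d", b, id0 + j),
                 age = a, period = a + b)
    })
    id0 <- id0 + n
    out[[ci]] <- do.call(rbind, rows)
  }
  rec <- do.call(rbind, out)
  mu <- curve_at(truth$age_curve, rec$age, "age_curve") +
    curve_at(truth$period_curve, rec$period, "period_curve") +
    curve_at(truth$cohort_curve, rec$period - rec$age, "cohort_curve")
  data.frame(
    child_id = rec$child_id, sex = sex, age = rec$age, period = rec$period,
    outcome_kind = outcome_kind,
    outcome = mu + stats::rnorm(nrow(rec), 0, truth$residual_sd),
    stringsAsFactors = FALSE
  )
}

#' Keep one randomly selected record per child
#'
#' Removes within-child correlation before aggregation by keeping exactly one
#' visit per distinct `child_id`, chosen uniformly at random.
#'
#' @param records data.frame of individual records with a `child_id` column.
#' @param seed integer RNG seed.
#' @return subset of `records`, one row per child, in first-appearance order
#'   of `child_id`.
#' @export
select_one_record_per_child <- function(records, seed = 1L) {
  if (nrow(records) == 0L) return(records)
  stopifnot("child_id" %in% names(records))
  set.seed(as.integer(seed))
  idx <- split(seq_len(nrow(records)), factor(records$child_id,
                                              levels = unique(records$child_id)))
  keep <- vapply(idx, function(i)
    if (length(i) == 1L) i else i[sample.int(length(i), 1L)], integer(1))
  records[unname(keep), , drop = FALSE]
}

#' Noise-free cell means implied by a truth
#'
#' The exact additive cell mean `age + period + cohort` for every (age,
#' period) cell of the design. Serves as the exact-recovery oracle for the
#' aggregation and fitting stages: with `residual_sd = 0`, aggregating a
#' generated population reproduces this table exactly.
#'
#' @inheritParams generate_population
#' @param sex label carried into the table.
#' @return a stratum table (see [aggregate_records()]) with `n = NA`
#'   (sentinel: not a sampled count) and `sd = 0`.
#' @export
truth_to_cell_means <- function(truth, design, sex = "male") {
  stopifnot(inherits(truth, "apc_truth"), inherits(design, "apc_design"))
  check_truth_covers(truth, design)
  g <- expand.grid(age = design$ages, period = design$periods,
                   KEEP.OUT.ATTRS = FALSE)
  k <- g$period - g$age
  tab <- data.frame(
    sex = sex, age = g$age, period = g$period, cohort_index = k,
    cohort_label = cohort_label(g$age, g$period),
    n = NA_integer_,
    mean = curve_at(truth$age_curve, g$age, "age_curve") +
      curve_at(truth$period_curve, g$period, "period_curve") +
      curve_at(truth$cohort_curve, k, "cohort_curve"),
    sd = 0,
    stringsAsFactors = FALSE
  )
  tab <- tab[order(tab$age, tab$period), , drop = FALSE]
  rownames(tab) <- NULL
  class(tab) <- c("stratum_table", "data.frame")
  tab
}

#' Write / read individual record files
#'
#' Records travel as tab-separated text with `#`-prefixed metadata header
#' lines (written first, skipped on read).
#'
#' @param records data.frame of individual records.
#' @param path file path.
#' @param meta named character vector written as `# key: value` lines.
#' @return `path`, invisibly (write); the records data.frame (read).
#' @export
write_records <- function(records, path, meta = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(meta))
    writeLines(paste0("# ", names(meta), ": ", meta), con)
  utils::write.table(records, con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_records
#' @export
read_records <- function(path) {
  utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
}
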