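#' Aggregate individual records into a stratum table
#'
#' Collapses individual health-check records to one row per (sex, age,
#' period) cell, carrying the cell count, mean and SD of the outcome and the
#' cohort index `period - age`. Records outside the design's age or period
#' grids are dropped with a message reporting the count; cells whose count
#' falls below `min_n` are dropped with a warning (the model fits cell
#' means, so near-empty cells carry almost no information). Empty cells are
#' simply absent from the table.
#'
#' @param records data.frame with columns `sex`, `age`, `period`, `outcome`.
#' @param design an [build_design()] object.
#' @param min_n minimum retained cell count (default 1).
#' @return a `stratum_table`: data.frame with columns `sex`, `age`, `period`,
#'   `cohort_index`, `cohort_label`, `n`, `mean`, `sd`, one row per occupied
#'   cell, ordered by sex, age, period. `sum(n)` equals the number of
#'   retained records before the `min_n` filter is applied to cells of
#'   count >= `min_n`.
#' @export
aggregate_records <- function(records, design, min_n = 1L) {
  stopifnot(inherits(design, "apc_design"))
  need <- c("sex", "age", "period", "outcome")
  if (!all(need %in% names(records)))
    stop("records must have columns: ", paste(need, collapse = ", "))
  inside <- records$age %in% design$ages & records$period %in% design$periods
  if (any(!inside))
    message(sum(!inside), " record(s) outside the design grids dropped")
  records <- records[inside, , drop = FALSE]
  if (nrow(records) == 0L)
    stop("no records fall inside the design grids; empty stratum table")

  key <- interaction(records$sex, records$age, records$period, drop = TRUE)
  first <- !duplicated(key)
  tab <- data.frame(
    sex = records$sex[first],
    age = records$age[first],
    period = records$period[first],
    n = as.integer(tabulate(key)[as.integer(key[first])]),
    mean = as.numeric(tapply(records$outcome, key, mean)[as.character(key[first])]),
    sd = as.numeric(tapply(records$outcome, key, stats::sd)[as.character(key[first])]),
    stringsAsFactors = FALSE
  )
  tab$cohort_index <- tab$period - tab$age
  tab$cohort_label <- cohort_label(tab$age, tab$period)
  tab <- tab[, c("sex", "age", "period", "cohort_index", "cohort_label",
                 "n", "mean", "sd")]
  low <- tab$n < min_n
  if (any(low)) {
    warning(sum(low), " cell(s) with n < ", min_n, " dropped")
    tab <- tab[!low, , drop = FALSE]
  }
  tab <- tab[order(tab$sex, tab$age, tab$period), , drop = FALSE]
  rownames(tab) <- NULL
  class(tab) <- c("stratum_table", "data.frame")
  tab
}

#' @rdname write_records
#' @param table a stratum table.
#' @export
write_stratum_table <- function(table, path, meta = NULL) {
  write_records(as.data.frame(table), path, meta)
}

#' @rdname write_records
#' @export
read_stratum_table <- function(path) {
  tab <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  class(tab) <- c("stratum_table", "data.frame")
  tab
}
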