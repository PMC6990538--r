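#' Published yearly mean BP and BMI series by sex and age group
#'
#' The published observed series of mean systolic/diastolic blood pressure
#' (mmHg, ages 9-18, 1999-2014) and mean BMI (kg/m2, ages 6-18, 1996-2014)
#' from the Hong Kong Student Health Service surveillance, by sex and broad
#' age group (childhood 9-11 / 6-11, adolescence 12-18). These aggregated
#' series are the worked-example input for the trend and joinpoint
#' operations; the underlying individual registry is restricted.
#'
#' @return data.frame with one row per examination year: `year`,
#'   `participation_rate` (%), and columns `<outcome>_<sex>_<agegroup>` for
#'   outcome in `sbp`, `dbp` (mmHg), `bmi` (kg/m2). Years before an
#'   outcome's collection window are `NA`.
#' @examples
#' tab1 <- shs_table1()
#' s <- tab1[!is.na(tab1$sbp_boys_9_11), c("year", "sbp_boys_9_11")]
#' s$year[which.min(s$sbp_boys_9_11)]  # 2004, the childhood SBP trough
#' @export
shs_table1 <- function() {
  path <- system.file("extdata", "shs_table1_means.csv", package = "apctrend",
                      mustWork = TRUE)
  utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
}
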