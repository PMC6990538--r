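# End-to-end pipeline plumbing: YAML config, seeded stage runners, delimited
# outputs with '#'-prefixed metadata headers, and a JSON run manifest.

#' Load a pipeline run configuration
#'
#' Reads a YAML file (or accepts a list) and fills defaults. Recognised
#' fields: `outcome_kind` (sbp|dbp|bmi), `sex` (male|female), design bounds
#' (`age_min`, `age_max`, `period_min`, `period_max`), `visits_per_child`,
#' `n_children_per_birth_year`, `seed`, MCMC settings (`chains`,
#' `iterations`, `weighting`, `prior_upper`), `horizon`, changepoint rules
#' (`credible_level`, `min_magnitude`, `max_joinpoints`), `truth` (optional
#' named year->value maps `age_curve`/`period_curve`/`cohort_curve` and
#' `residual_sd`), and paths (`records`, `table`, `out_dir`).
#'
#' @param config path to a YAML file, or a named list.
#' @return list of class `run_config` with defaults applied.
#' @export
load_config <- function(config) {
  cfg <- if (is.character(config)) yaml::read_yaml(config) else config
  stopifnot(is.list(cfg))
  defaults <- list(
    outcome_kind = "sbp", sex = "male",
    age_min = 9L, age_max = 18L, period_min = 1999L, period_max = 2014L,
    visits_per_child = 3L, n_children_per_birth_year = 200L, seed = 1L,
    chains = 5L, iterations = 2000L, weighting = "1", prior_upper = 100,
    horizon = 10L, credible_level = 0.95, min_magnitude = 0,
    max_joinpoints = 3L, allow_unconverged = FALSE
  )
  for (nm in names(defaults))
    if (is.null(cfg[[nm]])) cfg[[nm]] <- defaults[[nm]]
  class(cfg) <- c("run_config", "list")
  cfg
}

config_design <- function(cfg) {
  build_design(cfg$age_min, cfg$age_max, cfg$period_min, cfg$period_max)
}

config_truth <- function(cfg, design) {
  if (is.null(cfg$truth))
    return(default_truth(design, cfg$outcome_kind, cfg$sex))
  t <- cfg$truth
  as_curve <- function(x) stats::setNames(as.numeric(unlist(x)),
                                          names(unlist(x)))
  apc_truth(as_curve(t$age_curve), as_curve(t$period_curve),
            as_curve(t$cohort_curve), t$residual_sd %||% 1)
}

# small polynomial rolling hash of the canonicalised analytic config (paths
# excluded, so reruns into a different directory hash identically)
config_hash <- function(cfg) {
  cfg <- cfg[setdiff(names(cfg), c("records", "table", "out_dir"))]
  s <- paste(deparse(cfg[order(names(cfg))]), collapse = "")
  h <- 0
  for (b in utf8ToInt(s)) h <- (h * 131 + b) %% 2147483629
  sprintf("%08x", as.integer(h))
}

run_meta <- function(cfg) {
  c(config_hash = config_hash(cfg), seed = cfg$seed,
    outcome_kind = cfg$outcome_kind, sex = cfg$sex)
}

#' Simulate a synthetic record file from a configuration
#'
#' Wraps the synthetic-population generator: builds the design and truth
#' from the config, simulates the population, and writes the record table as
#' tab-separated text with the config hash and seed in the header.
#'
#' @param config a [load_config()] input.
#' @param path output file (default `records.tsv` under `out_dir`, or the
#'   config's `records` path).
#' @return invisibly, a list with `path`, `n_records`, `n_children`.
#' @export
run_simulate <- function(config, path = NULL) {
  cfg <- load_config(config)
  design <- config_design(cfg)
  truth <- config_truth(cfg, design)
  rec <- generate_population(truth, design,
                             visits_per_child = cfg$visits_per_child,
                             n_children_per_birth_year = cfg$n_children_per_birth_year,
                             seed = cfg$seed, sex = cfg$sex,
                             outcome_kind = cfg$outcome_kind)
  path <- path %||% cfg$records %||% file.path(cfg$out_dir %||% ".",
                                               "records.tsv")
  dir.create(dirname(path), showWarnings = FALSE, recursive = TRUE)
  write_records(rec, path, meta = run_meta(cfg))
  message("simulated ", nrow(rec), " records for ",
          length(unique(rec$child_id)), " children -> ", path)
  invisible(list(path = path, n_records = nrow(rec),
                 n_children = length(unique(rec$child_id))))
}

#' Run the tabulate-fit-project-changepoints pipeline
#'
#' Reads individual records (or a pre-aggregated stratum table), keeps one
#' random record per child, aggregates to stratum means, fits the Bayesian
#' APC model, extrapolates the configured horizon, computes yearly series,
#' curvature-based inflection flags and a joinpoint fit of the yearly
#' series, and writes every stage's table plus a JSON manifest to
#' `out_dir`. Non-convergence raises an error unless the config sets
#' `allow_unconverged: true` (the result is then flagged in the manifest).
#'
#' @param config a [load_config()] input; must provide `records` or `table`
#'   and `out_dir`.
#' @return invisibly, a list with the fit, projection, series, changepoint
#'   results and the manifest.
#' @export
run_fit_project <- function(config) {
  cfg <- load_config(config)
  design <- config_design(cfg)
  out_dir <- cfg$out_dir %||% stop("config needs an out_dir")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  meta <- run_meta(cfg)

  if (!is.null(cfg$table)) {
    if (!file.exists(cfg$table)) stop("stage tabulate: missing input ", cfg$table)
    tab <- read_stratum_table(cfg$table)
  } else {
    if (is.null(cfg$records) || !file.exists(cfg$records %||% ""))
      stop("stage tabulate: missing records file ",
           cfg$records %||% "(none given)")
    rec <- read_records(cfg$records)
    rec <- select_one_record_per_child(rec, seed = cfg$seed)
    tab <- aggregate_records(rec, design)
    write_stratum_table(tab, file.path(out_dir, "stratum_table.tsv"), meta)
  }

  fit <- fit_apc(tab, design, chains = cfg$chains,
                 iterations = cfg$iterations, seed = cfg$seed,
                 weighting = cfg$weighting, prior_upper = cfg$prior_upper)
  if (!isTRUE(fit$converged) && !isTRUE(cfg$allow_unconverged))
    stop("stage fit: chains not converged (max R-hat ",
         signif(fit$rhat_max, 4), "); rerun with more iterations or set ",
         "allow_unconverged")
  summ <- summarize_draws(fit)
  write_records(summ, file.path(out_dir, "posterior_summary.tsv"), meta)

  dic_tab <- compare_models(tab, design, models = cfg$models %||% "APC",
                            chains = cfg$chains, iterations = cfg$iterations,
                            seed = cfg$seed, weighting = cfg$weighting,
                            prior_upper = cfg$prior_upper)
  write_records(dic_tab, file.path(out_dir, "dic.tsv"), meta)

  ext <- extend_effects(fit, horizon = cfg$horizon, seed = cfg$seed)
  series <- yearly_mean_series(fit, ext)
  write_records(series, file.path(out_dir, "yearly_series.tsv"), meta)
  proj <- if (cfg$horizon > 0) project_cell_means(ext) else NULL
  if (!is.null(proj))
    write_records(proj$cells, file.path(out_dir, "projected_cells.tsv"), meta)

  cp <- list()
  for (e in intersect(c("age", "period", "cohort"), fit$effects)) {
    cv <- curvature(effect_draws(fit, e))
    infl <- inflection_points(cv, cfg$credible_level, cfg$min_magnitude)
    write_records(cv$series, file.path(out_dir, paste0("curvature_", e, ".tsv")),
                  meta)
    cp[[e]] <- list(curvature = cv, inflections = infl)
  }
  obs_y <- series$year[series$type == "observed"]
  # cap the joinpoint search at what the series length supports
  k_cap <- max(0L, (length(obs_y) - 2L) %/% 3L)
  jp <- joinpoint_fit(obs_y, series$mean[series$type == "observed"],
                      max_joinpoints = min(cfg$max_joinpoints, k_cap))
  write_records(data.frame(k = jp$k,
                           joinpoints = paste(jp$joinpoints, collapse = ","),
                           sse = jp$sse, mbic = jp$mbic),
                file.path(out_dir, "joinpoints.tsv"), meta)

  manifest <- list(
    package_version = as.character(utils::packageVersion("apctrend")),
    config_hash = unname(meta["config_hash"]), seed = cfg$seed,
    outcome_kind = cfg$outcome_kind, sex = cfg$sex,
    chains = fit$chains, iterations = fit$iterations,
    converged = fit$converged, rhat_max = fit$rhat_max,
    dic = dic_tab[, c("model", "Dbar", "pD", "DIC")],
    joinpoints = jp$joinpoints, n_strata = nrow(tab)
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(table = tab, fit = fit, summary = summ, dic = dic_tab,
                 extension = ext, projection = proj, series = series,
                 changepoints = cp, joinpoint = jp, manifest = manifest))
}
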