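#' End-to-end analysis pipeline
#'
#' Runs simulate -> match -> estimate -> model -> CEA -> DSA -> PSA from a
#' single configuration, writing every stage's table under a fresh output
#' directory and a manifest last. Any stage failure aborts with a
#' stage-labeled error; a successful run is fully reproducible from the
#' seeds in the manifest.
#'
#' @param config A list (or path to a YAML file) with optional entries:
#'   `out_dir` (must not already exist; a timestamped directory under
#'   `tempdir()` is used when omitted), `seed`, `cohort_config` (path to a
#'   cohort YAML), `params` (path to a model-parameter YAML/JSON),
#'   `value_set` (path to a tariff CSV; the synthetic additive tariff when
#'   omitted), `use_cohort_estimates` (default TRUE: matched-cohort
#'   utilities and admission costs feed the model), `psm_covariates`,
#'   `caliper_sd_mult`, `psa_iterations`, `dsa_wtp_ref`, `horizon`.
#' @return A run manifest (list): seeds, package version, per-stage output
#'   files, stage timings (seconds), and diagnostics counts.
#' @export
run_pipeline <- function(config = list()) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  allowed <- c("out_dir", "seed", "cohort_config", "params", "value_set",
               "use_cohort_estimates", "psm_covariates", "caliper_sd_mult",
               "psa_iterations", "dsa_wtp_ref", "horizon")
  extra <- setdiff(names(config), allowed)
  if (length(extra)) stopf("unknown pipeline-config key(s): %s", paste(extra, collapse = ", "))

  out_dir <- config$out_dir %||%
    file.path(tempdir(), format(Sys.time(), "bttcea-run-%Y%m%d-%H%M%OS3"))
  if (dir.exists(out_dir)) stopf("output directory already exists: %s", out_dir)
  for (p in c(config$cohort_config, config$params, config$value_set))
    if (!file.exists(p)) stopf("pre-flight: input file missing: %s", p)
  dir.create(out_dir, recursive = TRUE)

  seed <- config$seed %||% 1L
  files <- list(); timings <- list(); diagnostics <- list()
  stage <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    res <- tryCatch(force(expr),
                    error = function(e) stopf("stage [%s] failed: %s", name,
                                              conditionMessage(e)))
    timings[[name]] <<- round(proc.time()[["elapsed"]] - t0, 3)
    res
  }
  emit <- function(obj, name) {
    path <- file.path(out_dir, name)
    utils::write.csv(obj, path, row.names = FALSE)
    files[[length(files) + 1L]] <<- name
    invisible(path)
  }

  cohort_cfg <- stage("config", {
    if (!is.null(config$cohort_config)) read_cohort_config(config$cohort_config)
    else cohort_config(seed = seed)
  })
  vs <- stage("value_set", {
    if (!is.null(config$value_set)) read_value_set(config$value_set)
    else synthetic_value_set()
  })
  params <- stage("params", {
    if (!is.null(config$params)) read_model_params(config$params)
    else default_model_params()
  })

  cohort <- stage("simulate", generate_cohort(cohort_cfg))
  emit(cohort, "cohort.csv")

  covs <- config$psm_covariates %||% default_psm_covariates()
  fit <- stage("propensity", fit_propensity(cohort, covs))
  matched <- stage("match",
                   nearest_neighbor_match(fit, config$caliper_sd_mult %||% 0.2))
  emit(matched$pairs, "matches.csv")
  balance <- stage("balance", balance_diagnostics(cohort, matched, covs))
  emit(balance, "balance.csv")
  diagnostics$records_dropped <- length(fit$dropped)
  diagnostics$unmatched_treated <- length(matched$unmatched_treated)

  use_est <- config$use_cohort_estimates %||% TRUE
  specs <- stage("assemble", {
    matched_ids <- c(matched$pairs$treated_id, matched$pairs$control_id)
    mc <- cohort[cohort$id %in% matched_ids, ]
    cpi <- china_cpi_table()
    lapply(stats::setNames(nm = arm_levels), function(a) {
      est <- NULL
      if (isTRUE(use_est)) {
        grp <- mc[mc$arm == a, ]
        infl <- vapply(grp$total_cost, inflate_to_2023, numeric(1),
                       year = unique(grp$cost_year), cpi_table = cpi)
        q <- stats::quantile(infl, c(0.25, 0.75), names = FALSE)
        est <- list(utility = mean_utility(grp, vs),
                    onetime_cost = list(mean = mean(infl), q1 = q[1], q3 = q[2]))
      }
      assemble_model(a, params, cohort_estimates = est)
    })
  })

  results <- stage("model", lapply(specs, run_arm))
  for (a in arm_levels)
    emit(as.data.frame(unclass(results[[a]]$trace)),
         sprintf("trace_%s.csv", tolower(a)))
  cea <- stage("cea", cea_table(results$tMCS, results$HTx))
  files <- c(files, write_tables(cea, out_dir, "cea"))

  horizon <- config$horizon %||% 10
  dsa <- stage("dsa", one_way_dsa(specs$tMCS, specs$HTx,
                                  wtp_ref = config$dsa_wtp_ref %||%
                                    specs$tMCS$gdp_per_capita,
                                  horizon = horizon))
  emit(dsa$entries, "tornado.csv")
  diagnostics$dsa_skipped <- length(dsa$skipped)

  psa <- stage("psa", sample_psa(specs$tMCS, specs$HTx,
                                 psa_config(config$psa_iterations %||% 1000,
                                            seed = seed),
                                 horizon = horizon))
  emit(psa$samples, "psa_samples.csv")
  emit(ce_plane(psa), "ce_plane.csv")
  emit(ceac(psa), "ceac.csv")
  diagnostics$psa_resampled <- psa$n_resampled

  manifest <- list(seed = seed, cohort_seed = cohort_cfg$seed,
                   package_version = as.character(utils::packageVersion("bttcea")),
                   out_dir = out_dir, files = unlist(files),
                   timings = timings, diagnostics = diagnostics)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}

#' Serialize a CEA table as CSV and JSON twins
#'
#' Monetary columns are rounded to 2 decimals at serialization only;
#' undefined ICERs are encoded through their dominance label, never as a
#' number.
#'
#' @param cea A `cea_result` data frame.
#' @param dir Output directory.
#' @param stem File stem (writes `<stem>.csv` and `<stem>.json`).
#' @return The two file names, invisibly.
#' @export
write_tables <- function(cea, dir, stem = "cea") {
  out <- cea
  money <- c("cost_tMCS", "cost_HTx", "delta_cost", "icer")
  for (m in intersect(money, names(out))) out[[m]] <- round(out[[m]], 2)
  for (q in intersect(c("qaly_tMCS", "qaly_HTx", "delta_qaly"), names(out)))
    out[[q]] <- round(out[[q]], 4)
  out$icer <- ifelse(out$icer_label == "icer", as.character(out$icer), out$icer_label)
  csv <- file.path(dir, paste0(stem, ".csv"))
  json <- file.path(dir, paste0(stem, ".json"))
  utils::write.csv(out, csv, row.names = FALSE, quote = FALSE)
  jsonlite::write_json(out, json, auto_unbox = TRUE, digits = NA, dataframe = "rows")
  invisible(paste0(stem, c(".csv", ".json")))
}
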