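#' Pipeline run configuration
#'
#' Assembles and validates the settings for [run_pipeline()]: the synthetic
#' cohort size and seed, which outcomes to analyze, the candidate predictor
#' and forced covariate columns, QC / screening / selection thresholds, and
#' MSM settings. Unknown fields are rejected so config typos fail before any
#' compute.
#'
#' @param n_participants synthetic cohort size.
#' @param seed global seed; per-stage seeds are derived by fixed offsets.
#' @param outcomes outcome names to analyze (subset of the spec names).
#' @param candidates candidate time-varying predictor columns.
#' @param prs_cols PRS columns (exempt from QC, forced into the
#'   multivariable model).
#' @param forced_cols forced covariate columns (sex, baseline age, PCs).
#' @param strata_col stratification column for the multivariable model.
#' @param freq_threshold,r_threshold,p_enter,min_frac,k_folds QC and
#'   selection thresholds.
#' @param msm_exposures named character vector exposure column -> type
#'   (`"binary"` or `"median_split"`).
#' @param msm_l_cols time-varying confounder columns for the weight
#'   denominator model.
#' @param clip,trunc_q weight estimation settings.
#' @param miss_rate_visit,miss_rate_cell missingness rates for the synthetic
#'   cohort.
#' @param ... must be empty; unknown settings are an error.
#' @return a `run_config` list.
#' @export
run_config <- function(n_participants = 500,
                       seed = 20260101,
                       outcomes = c("alcohol", "nicotine", "cannabis", "any"),
                       candidates = c(paste0("beh_x", 1:5), "par_monitor",
                                      "conf_ar", "expo_bin"),
                       prs_cols = paste0("prs_", 1:4),
                       forced_cols = NULL,
                       strata_col = "site",
                       freq_threshold = 0.99, r_threshold = 0.9,
                       p_enter = 0.05, min_frac = 0.5, k_folds = 10,
                       msm_exposures = c(par_monitor = "median_split",
                                         expo_bin = "binary"),
                       msm_l_cols = "conf_ar",
                       clip = 0.01, trunc_q = 0.99,
                       miss_rate_visit = 0.1, miss_rate_cell = 0.1,
                       ...) {
  extra <- list(...)
  if (length(extra)) {
    stop(sprintf("unknown configuration field(s): %s",
                 paste(names(extra), collapse = ", ")), call. = FALSE)
  }
  cfg <- list(n_participants = n_participants, seed = seed,
              outcomes = outcomes, candidates = candidates,
              prs_cols = prs_cols, forced_cols = forced_cols,
              strata_col = strata_col, freq_threshold = freq_threshold,
              r_threshold = r_threshold, p_enter = p_enter,
              min_frac = min_frac, k_folds = k_folds,
              msm_exposures = msm_exposures, msm_l_cols = msm_l_cols,
              clip = clip, trunc_q = trunc_q,
              miss_rate_visit = miss_rate_visit,
              miss_rate_cell = miss_rate_cell)
  class(cfg) <- "run_config"
  cfg
}

#' Read a run configuration from a YAML file
#'
#' @param path YAML file whose keys are [run_config()] arguments.
#' @return a `run_config`.
#' @export
read_run_config <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE)) {
    stop("the 'yaml' package is required to read YAML configs")
  }
  vals <- yaml::read_yaml(path)
  if (!is.null(vals$msm_exposures)) {
    vals$msm_exposures <- unlist(vals$msm_exposures)
  }
  do.call(run_config, vals)
}

#' Run the full analysis pipeline on a synthetic cohort
#'
#' Executes simulate -> derive outcomes -> build intervals -> predictor QC ->
#' univariate screen -> LASSO selection -> multivariable Cox -> MSM-IPTW,
#' writing per-outcome TSV result tables, a QC report, a JSON manifest
#' (package version, seed, thresholds, output checksums) and a plain-text
#' log under `out_dir`. Identical config and seed produce identical output
#' checksums.
#'
#' @param config a [run_config()].
#' @param out_dir output directory (created).
#' @return (invisibly) a list with the in-memory stage results and
#'   `out_dir`.
#' @export
run_pipeline <- function(config = run_config(), out_dir = tempfile("run_")) {
  stopifnot(inherits(config, "run_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(out_dir, "pipeline.log")
  logf <- function(fmt, ...) {
    cat(sprintf(paste0(fmt, "\n"), ...), file = log_path, append = TRUE)
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE)
    })
  }
  cat(sprintf("pipeline run, seed %d\n", config$seed), file = log_path)

  # stage 1: simulate (seed + 0; truth simulation internally uses seed + 1)
  cohort <- stage("simulate", {
    generate_cohort(sim_config(
      n_participants = config$n_participants, seed = config$seed,
      miss_rate_visit = config$miss_rate_visit,
      miss_rate_cell = config$miss_rate_cell, compute_truth = FALSE))
  })
  logf("simulated %d participants, %d visit rows", nrow(cohort$baseline),
       nrow(cohort$long))
  if (is.null(config$forced_cols)) {
    config$forced_cols <- c("sex", "baseline_age_months",
                            grep("^pc_", names(cohort$baseline),
                                 value = TRUE))
  }

  # stage 2: outcomes
  specs <- default_outcome_specs()[config$outcomes]
  src <- split_sources(cohort$long)
  harm <- stage("derive-outcomes",
                harmonize_sources(src$annual, src$phone))
  outcomes <- stage("derive-outcomes", derive_outcomes(harm, specs))
  for (nm in names(outcomes)) {
    utils::write.csv(outcomes[[nm]],
                     file.path(out_dir, sprintf("outcome_%s.csv", nm)),
                     row.names = FALSE)
    logf("outcome %s: %d cases / %d participants", nm,
         sum(outcomes[[nm]]$event), nrow(outcomes[[nm]]))
  }

  # stage 3: QC on the visit-level candidates
  qc <- stage("qc", qc_predictors(cohort$long, config$candidates,
                                  exempt = config$prs_cols,
                                  freq_threshold = config$freq_threshold,
                                  r_threshold = config$r_threshold))
  utils::write.table(qc$report, file.path(out_dir, "qc_report.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  logf("qc kept %d/%d candidates", length(qc$kept),
       length(config$candidates))

  results <- list()
  for (nm in names(outcomes)) {
    res <- stage(paste0("analyze-", nm), {
      analyze_outcome(cohort, outcomes[[nm]], qc$kept, config, out_dir, nm,
                      logf)
    })
    results[[nm]] <- res
  }

  # manifest with output checksums
  files <- sort(setdiff(list.files(out_dir), c("manifest.json",
                                               "pipeline.log")))
  manifest <- list(
    package = "initsurv",
    version = as.character(utils::packageVersion("initsurv")),
    seed = config$seed,
    config = unclass(config),
    files = as.list(stats::setNames(
      unname(tools::md5sum(file.path(out_dir, files))), files)))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(cohort = cohort, outcomes = outcomes, qc = qc,
                 results = results, out_dir = out_dir))
}

# per-outcome modeling: intervals, screen, selection, multivariable, MSM
analyze_outcome <- function(cohort, outcome, candidates, config, out_dir,
                            nm, logf = function(...) invisible()) {
  long <- forward_fill(cohort$long, cols = candidates)
  iv_raw <- build_interval_table(long, outcome,
                                 covariate_cols = candidates)
  iv_raw <- attach_baseline(iv_raw, cohort$baseline)
  iv <- encode_value_availability(iv_raw, candidates)
  enc <- attr(iv, "encoded")

  scr <- screen_univariate(iv, c(enc, config$prs_cols),
                           forced_cols = config$forced_cols)
  write_results_tsv(scr, file.path(out_dir, sprintf("screen_%s.tsv", nm)))
  logf("%s: screened %d predictors, %d FDR-significant", nm, nrow(scr),
       sum(scr$q < 0.05, na.rm = TRUE))

  pre <- prescreen(scr, cohort$long, p_enter = config$p_enter,
                   min_frac = config$min_frac)
  pre <- setdiff(pre, config$prs_cols)
  sel <- if (length(pre)) {
    suppressWarnings(
      lasso_screen(iv, pre, forced_cols = config$forced_cols,
                   k_folds = config$k_folds, seed = config$seed + 2L))
  } else character(0)
  logf("%s: prescreen kept %d, lasso selected %d", nm, length(pre),
       length(sel))

  multi <- fit_multivariable(iv, c(sel, config$prs_cols),
                             forced_cols = config$forced_cols,
                             strata_col = config$strata_col)
  write_results_tsv(multi, file.path(out_dir,
                                     sprintf("multivar_%s.tsv", nm)))

  msm_rows <- lapply(names(config$msm_exposures), function(ex) {
    if (!ex %in% names(iv)) return(NULL)
    run_msm_exposure(iv, ex, z_cols = setdiff(config$forced_cols,
                                              config$strata_col),
                     l_cols = intersect(config$msm_l_cols, names(iv)),
                     type = config$msm_exposures[[ex]],
                     clip = config$clip, trunc_q = config$trunc_q)
  })
  msm <- do.call(rbind, Filter(Negate(is.null), msm_rows))
  if (!is.null(msm)) {
    msm <- fdr_across_exposures(msm)
    utils::write.table(
      msm[c("exposure", "psi", "OR", "ci_low", "ci_high", "p", "q",
            "mean_w", "max_w", "ess_ratio", "retained")],
      file.path(out_dir, sprintf("msm_%s.tsv", nm)),
      sep = "\t", row.names = FALSE, quote = FALSE)
    logf("%s: msm retained %d/%d exposures", nm, sum(msm$retained),
         nrow(msm))
  }
  list(intervals = iv, screen = scr, selected = sel, multivariable = multi,
       msm = msm)
}

#' Domain-level counts of significant predictors
#'
#' Tallies, per predictor domain, how many predictors are FDR-significant
#' (`q < alpha`) and how many additionally meet the Bonferroni threshold.
#' Predictors without a domain label are counted under `"other"` (with a
#' message).
#'
#' @param screen a `screen_result` with `q` and `p_bonf` columns.
#' @param domain_map named character vector predictor -> domain (optional if
#'   the result already carries domains).
#' @param alpha significance level (default 0.05).
#' @return data frame `domain, n_fdr, n_bonferroni`.
#' @export
render_domain_summary <- function(screen, domain_map = NULL, alpha = 0.05) {
  dom <- if (!is.null(domain_map)) unname(domain_map[screen$predictor]) else
    screen$domain
  if (is.null(dom)) dom <- rep(NA_character_, nrow(screen))
  n_unlab <- sum(is.na(dom))
  if (n_unlab > 0) {
    message(sprintf("render_domain_summary: %d unlabeled predictor(s) counted under 'other'",
                    n_unlab))
    dom[is.na(dom)] <- "other"
  }
  fdr <- !is.na(screen$q) & screen$q < alpha
  bon <- !is.na(screen$p_bonf) & screen$p_bonf < alpha
  doms <- sort(unique(dom))
  data.frame(
    domain = doms,
    n_fdr = vapply(doms, function(d) sum(fdr & dom == d), 0L),
    n_bonferroni = vapply(doms, function(d) sum(bon & dom == d), 0L),
    row.names = NULL, stringsAsFactors = FALSE)
}
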