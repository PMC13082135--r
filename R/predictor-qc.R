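#' Predictor quality-control filters
#'
#' Minimal filtering of candidate predictors before modeling: drop columns
#' that are entirely missing, near-constant numeric columns, and one member
#' of each highly collinear pair. Forced covariates are exempt. Each
#' function returns the filtered table plus a `qc_report` data frame with
#' one disposition per input predictor.
#'
#' @name predictor_qc
NULL

qc_report_row <- function(predictor, disposition, partner = NA_character_,
                          abs_r = NA_real_) {
  data.frame(predictor = predictor, disposition = disposition,
             partner = partner, abs_r = abs_r, stringsAsFactors = FALSE)
}

#' Drop entirely missing predictors
#'
#' @param table data frame.
#' @param cols candidate predictor columns (default: all numeric columns).
#' @return list `table` (filtered) and `report` (`qc_report`).
#' @export
drop_all_missing <- function(table, cols = NULL) {
  cols <- cols %||% names(table)[vapply(table, function(v) {
    is.numeric(v) || all(is.na(v))
  }, TRUE)]
  rep_ <- lapply(cols, function(cc) {
    if (all(is.na(table[[cc]]))) qc_report_row(cc, "all_missing")
    else qc_report_row(cc, "kept")
  })
  report <- do.call(rbind, rep_)
  drop <- report$predictor[report$disposition == "all_missing"]
  table[drop] <- NULL
  list(table = table, report = report)
}

#' Drop near-constant numeric predictors
#'
#' A numeric column is near-constant when its modal value accounts for at
#' least `freq_threshold` of the non-missing cells (default 0.99).
#'
#' @inheritParams drop_all_missing
#' @param freq_threshold modal-frequency threshold in (0.5, 1].
#' @return list `table` and `report`.
#' @export
drop_near_constant <- function(table, cols = NULL, freq_threshold = 0.99) {
  stopifnot(freq_threshold > 0.5, freq_threshold <= 1)
  cols <- cols %||% names(table)[vapply(table, is.numeric, TRUE)]
  rep_ <- lapply(cols, function(cc) {
    v <- table[[cc]]
    v <- v[!is.na(v)]
    if (!length(v)) return(qc_report_row(cc, "kept"))
    modal <- max(tabulate(match(v, unique(v)))) / length(v)
    if (modal >= freq_threshold) qc_report_row(cc, "near_constant")
    else qc_report_row(cc, "kept")
  })
  report <- do.call(rbind, rep_)
  table[report$predictor[report$disposition == "near_constant"]] <- NULL
  list(table = table, report = report)
}

#' Drop one member of each highly collinear pair
#'
#' Computes pairwise-complete Pearson correlations among the candidate
#' columns and, in a single greedy pass over pairs sorted by |r| descending,
#' drops the later column (input order) of any pair with |r| above the
#' threshold whose earlier member is still retained.
#'
#' @inheritParams drop_all_missing
#' @param r_threshold absolute correlation threshold (default 0.9).
#' @return list `table` and `report` (dropped rows carry the kept partner
#'   and |r|).
#' @export
drop_collinear <- function(table, cols = NULL, r_threshold = 0.9) {
  cols <- cols %||% names(table)[vapply(table, is.numeric, TRUE)]
  cols <- cols[vapply(cols, function(cc) sum(!is.na(table[[cc]])) >= 2, TRUE)]
  keep <- rep(TRUE, length(cols))
  names(keep) <- cols
  pairs <- NULL
  if (length(cols) >= 2) {
    cm <- suppressWarnings(
      stats::cor(table[cols], use = "pairwise.complete.obs"))
    cm[!is.finite(cm)] <- 0
    ut <- which(upper.tri(cm), arr.ind = TRUE)
    r <- abs(cm[ut])
    ord <- order(r, decreasing = TRUE)
    ut <- ut[ord, , drop = FALSE]; r <- r[ord]
    hit <- r > r_threshold
    ut <- ut[hit, , drop = FALSE]; r <- r[hit]
    if (nrow(ut)) {
      pairs <- data.frame(a = cols[ut[, 1]], b = cols[ut[, 2]], r = r,
                          stringsAsFactors = FALSE)
      for (i in seq_len(nrow(pairs))) {
        a <- pairs$a[i]; b <- pairs$b[i]
        # drop the later column in input order if both still retained
        first <- if (match(a, cols) <= match(b, cols)) a else b
        later <- setdiff(c(a, b), first)
        if (keep[[first]] && keep[[later]]) keep[[later]] <- FALSE
      }
    }
  }
  rep_ <- lapply(cols, function(cc) {
    if (keep[[cc]]) return(qc_report_row(cc, "kept"))
    i <- which((pairs$a == cc | pairs$b == cc))[1]
    partner <- setdiff(c(pairs$a[i], pairs$b[i]), cc)[1]
    qc_report_row(cc, "collinear_dropped", partner, pairs$r[i])
  })
  report <- do.call(rbind, rep_)
  table[cols[!keep]] <- NULL
  list(table = table, report = report)
}

#' Coverage filter: observed at least once in enough participants
#'
#' A predictor passes when the fraction of participants with at least one
#' observed (pre-imputation) value is at least `min_frac`. Baseline-only
#' measures observed once per participant therefore pass.
#'
#' @param table long or interval table with an `id` column and raw
#'   (pre-imputation) predictor values.
#' @param predictors predictor columns to assess.
#' @param min_frac minimum fraction of participants (default 0.5).
#' @param id_col participant identifier column.
#' @return character vector of predictors passing the filter, with the
#'   per-predictor coverage fractions as `attr(, "coverage")`.
#' @export
coverage_filter <- function(table, predictors, min_frac = 0.5,
                            id_col = "id") {
  n_ids <- length(unique(table[[id_col]]))
  cov <- vapply(predictors, function(cc) {
    ok <- !is.na(table[[cc]])
    length(unique(table[[id_col]][ok])) / n_ids
  }, 0)
  kept <- predictors[cov >= min_frac]
  attr(kept, "coverage") <- cov
  kept
}

#' Run the full predictor QC pipeline
#'
#' Applies [drop_all_missing()], [drop_near_constant()] and
#' [drop_collinear()] in order, exempting forced covariates and PRS columns
#' from every filter. The pipeline is idempotent.
#'
#' @param table data frame of candidate predictors (long format).
#' @param candidates candidate predictor columns.
#' @param exempt columns never filtered (forced covariates, PRS).
#' @param freq_threshold,r_threshold thresholds for the component filters.
#' @return list `table`, `kept` (surviving candidate names) and `report`
#'   (one disposition per candidate).
#' @export
qc_predictors <- function(table, candidates = NULL, exempt = character(0),
                          freq_threshold = 0.99, r_threshold = 0.9) {
  candidates <- candidates %||%
    setdiff(names(table)[vapply(table, is.numeric, TRUE)],
            c("visit_order", "interview_age_months", "start", "stop",
              "event_interval"))
  candidates <- setdiff(candidates, exempt)
  s1 <- drop_all_missing(table, candidates)
  c1 <- s1$report$predictor[s1$report$disposition == "kept"]
  s2 <- drop_near_constant(s1$table, c1, freq_threshold)
  c2 <- s2$report$predictor[s2$report$disposition == "kept"]
  s3 <- drop_collinear(s2$table, c2, r_threshold)
  report <- rbind(
    s1$report[s1$report$disposition != "kept", ],
    s2$report[s2$report$disposition != "kept", ],
    s3$report)
  report <- report[!duplicated(report$predictor), ]
  rownames(report) <- NULL
  list(table = s3$table,
       kept = report$predictor[report$disposition == "kept"],
       report = report)
}
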