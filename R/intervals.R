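#' Months of follow-up since baseline
#'
#' @param interview_age_months interview age at the visit, in months.
#' @param baseline_age_months interview age at baseline, in months.
#' @return `interview_age_months - baseline_age_months`, always >= 0.
#' @export
compute_time_months <- function(interview_age_months, baseline_age_months) {
  if (any(interview_age_months < 0, na.rm = TRUE) ||
      any(baseline_age_months < 0, na.rm = TRUE)) {
    stop("ages must be non-negative", call. = FALSE)
  }
  d <- interview_age_months - baseline_age_months
  if (any(d < 0, na.rm = TRUE)) {
    stop("data error: visit predates baseline (negative follow-up time)",
         call. = FALSE)
  }
  d
}

#' Build counting-process start-stop intervals for one participant
#'
#' Given the participant's observed visit times (months since baseline,
#' already restricted to <= the follow-up time `T`), constructs consecutive
#' intervals: `start_1 = 0`, `start_i = t_i` for i > 1, `stop_i = t_{i+1}`
#' for i < n and `stop_n = T`. If the first visit falls after month 0 a
#' baseline row at time 0 is created that copies the earliest observation
#' (tracked via `visit_index`). Zero-length intervals (`stop <= start`) are
#' excluded, and the event indicator is 1 only on the final retained interval
#' when `event = 1`.
#'
#' @param visit_times sorted ascending visit times in months, all <= `T`.
#' @param T follow-up time in months (event or censoring).
#' @param event 0/1 event indicator at `T`.
#' @return data frame with `start`, `stop`, `event_interval` and
#'   `visit_index` (the index into `visit_times` whose observation supplies
#'   the interval's covariates; the baseline copy uses index 1).
#' @export
build_intervals <- function(visit_times, T, event) {
  if (length(visit_times) == 0) stop("empty visit list", call. = FALSE)
  if (is.na(T) || T < 0) stop("follow-up time T must be >= 0", call. = FALSE)
  if (is.unsorted(visit_times, strictly = FALSE)) {
    stop("visit_times must be sorted ascending", call. = FALSE)
  }
  if (any(visit_times > T)) {
    stop("visit_times must not exceed the follow-up time T", call. = FALSE)
  }
  idx <- seq_along(visit_times)
  if (visit_times[1] > 0) {       # common time origin: copy earliest visit
    visit_times <- c(0, visit_times)
    idx <- c(1L, idx)
  }
  n <- length(visit_times)
  start <- c(0, visit_times[-1])
  stop_ <- c(visit_times[-1], T)
  keep <- stop_ > start
  out <- data.frame(start = start[keep], stop = stop_[keep],
                    event_interval = 0L, visit_index = idx[keep])
  if (nrow(out) == 0) return(out)
  if (event == 1) out$event_interval[nrow(out)] <- 1L
  out
}

#' Build an interval table for a whole cohort and one outcome
#'
#' Joins the visit-level long table (covariates at each visit) with
#' per-participant survival outcomes and expands each participant into
#' counting-process rows via [build_intervals()]. Covariates are frozen at
#' the interval's start visit (the baseline-copy row reuses the earliest
#' observation; ties between event time and a visit time resolve to the
#' earlier visit, so there is no look-ahead).
#'
#' @param long visit-level table with `id`, `visit`, `interview_age_months`
#'   and covariate columns.
#' @param outcome data frame from [derive_outcome()] (`id`, `time_months`,
#'   `event`, `status`); rows with `status == "missing"` and `event == 0`
#'   are still intervalized (censored at their last visit) unless
#'   `drop_missing_status = TRUE`.
#' @param covariate_cols covariate columns to carry; default all non-key
#'   columns of `long`.
#' @param visit_levels ordered visit labels.
#' @param drop_missing_status exclude participants with missing case-control
#'   status.
#' @return data frame `id, start, stop, event_interval, <covariates>`.
#' @export
build_interval_table <- function(long, outcome, covariate_cols = NULL,
                                 visit_levels = default_visit_levels(),
                                 drop_missing_status = FALSE) {
  if (is.null(covariate_cols)) {
    covariate_cols <- setdiff(names(long),
                              c("id", "visit", "interview_age_months",
                                "visit_order"))
  }
  if (drop_missing_status) {
    outcome <- outcome[outcome$status != "missing", , drop = FALSE]
  }
  if (!"visit_order" %in% names(long)) {
    long$visit_order <- match(long$visit, visit_levels)
  }
  long <- long[order(long$id, long$visit_order), , drop = FALSE]
  by_id <- split(seq_len(nrow(long)), long$id)
  pieces <- vector("list", nrow(outcome))
  for (i in seq_len(nrow(outcome))) {
    pid <- outcome$id[i]
    ix <- by_id[[pid]]
    if (is.null(ix)) next
    age <- long$interview_age_months[ix]
    tt <- compute_time_months(age, age[1])
    Tfu <- outcome$time_months[i]
    sel <- which(tt <= Tfu)
    if (!length(sel)) sel <- 1L   # late first visit relative to T=0.5 events
    iv <- build_intervals(tt[sel], Tfu, outcome$event[i])
    if (nrow(iv) == 0) next
    cov <- long[ix[sel][iv$visit_index], covariate_cols, drop = FALSE]
    pieces[[i]] <- cbind(data.frame(id = pid, start = iv$start,
                                    stop = iv$stop,
                                    event_interval = iv$event_interval,
                                    stringsAsFactors = FALSE),
                         cov)
  }
  out <- do.call(rbind, pieces)
  if (is.null(out)) {
    out <- cbind(data.frame(id = character(0), start = numeric(0),
                            stop = numeric(0), event_interval = integer(0)),
                 long[0, covariate_cols, drop = FALSE])
  }
  rownames(out) <- NULL
  out
}

#' Forward-fill covariates within participant (LOCF)
#'
#' Propagates each participant's last observed value to later rows only;
#' no back-filling into earlier time points is performed, so no future
#' information leaks into past intervals.
#'
#' @param table long table sorted by (id, time) or any table plus `id_col`.
#' @param cols columns to fill; default all non-key numeric columns.
#' @param id_col participant identifier column.
#' @return the table with `cols` forward-filled within `id_col`.
#' @export
forward_fill <- function(table, cols = NULL, id_col = "id") {
  if (is.null(cols)) {
    cols <- setdiff(names(table),
                    c(id_col, "visit", "visit_order", "interview_age_months",
                      "start", "stop", "event_interval"))
    cols <- cols[vapply(table[cols], is.numeric, TRUE)]
  }
  grp <- table[[id_col]]
  new_grp <- c(TRUE, grp[-1] != grp[-length(grp)])
  for (cc in cols) {
    v <- table[[cc]]
    keep <- !is.na(v) | new_grp          # positions that break the carry
    idx <- cumsum(keep)                  # last carry-breaking position
    src <- which(keep)[idx]
    filled <- v[src]
    # carry-breaking positions that are NA (new id with NA) stay NA
    table[[cc]] <- filled
  }
  table
}

#' Value + availability encoding for intermittently missing predictors
#'
#' For each predictor X adds an observedness indicator `X_obs` (1 if the cell
#' was observed, 0 otherwise) and replaces missing values with the median of
#' observed values (pooled over all rows by default, or within visit when
#' `per_visit = TRUE`). Predictors with no observed values are dropped with a
#' warning (their median is undefined). Intended to run after
#' [forward_fill()], so the indicator marks cells that no earlier observation
#' could fill.
#'
#' @param table long or interval table.
#' @param predictors predictor columns to encode.
#' @param per_visit compute medians within `visit` instead of pooled.
#' @return the table with imputed predictors and `<X>_obs` companions; kept
#'   predictor names are in `attr(, "encoded")`.
#' @export
encode_value_availability <- function(table, predictors,
                                      per_visit = FALSE) {
  kept <- character(0)
  for (cc in predictors) {
    v <- table[[cc]]
    if (all(is.na(v))) {
      warning(sprintf("predictor '%s' has no observed values; dropped", cc),
              call. = FALSE)
      table[[cc]] <- NULL
      next
    }
    obs <- as.integer(!is.na(v))
    if (per_visit && "visit" %in% names(table)) {
      med <- stats::ave(v, table$visit,
                        FUN = function(x) stats::median(x, na.rm = TRUE))
      v[is.na(v)] <- med[is.na(v)]
      v[is.na(v)] <- stats::median(table[[cc]], na.rm = TRUE)
    } else {
      v[is.na(v)] <- stats::median(v, na.rm = TRUE)
    }
    table[[cc]] <- v
    table[[paste0(cc, "_obs")]] <- obs
    kept <- c(kept, cc)
  }
  attr(table, "encoded") <- kept
  table
}

#' Replicate baseline-only columns across all of a participant's rows
#'
#' Time-invariant measures (PRS, baseline covariates) are carried across all
#' time intervals for each participant.
#'
#' @param table table with an `id` column.
#' @param baseline one row per participant with `id` plus the columns to
#'   replicate.
#' @param cols columns of `baseline` to attach; default all non-id columns.
#' @return `table` with the baseline columns joined on `id`.
#' @export
attach_baseline <- function(table, baseline, cols = NULL) {
  if (is.null(cols)) cols <- setdiff(names(baseline), "id")
  m <- match(table$id, baseline$id)
  for (cc in cols) table[[cc]] <- baseline[[cc]][m]
  table
}
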