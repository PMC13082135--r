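#' Define a substance initiation outcome
#'
#' Names the endorsement items whose first affirmative response marks
#' initiation, any religious-context flag columns (an endorsement whose flag
#' is set is masked to missing before aggregation), and the visit labels used
#' for censoring (FU4) and for anchoring control status (FU3).
#'
#' @param substance outcome name.
#' @param items character vector of endorsement item columns.
#' @param religious_flags named character vector mapping item column ->
#'   religious-context flag column, or `NULL`.
#' @param censor_visit visit label at which follow-up is censored.
#' @param control_visit visit label whose observation is required for
#'   control status.
#' @return an `outcome_spec` object.
#' @export
outcome_spec <- function(substance, items, religious_flags = NULL,
                         censor_visit = "FU4", control_visit = "FU3") {
  stopifnot(is.character(items), length(items) >= 1)
  if (!is.null(religious_flags)) {
    stopifnot(!is.null(names(religious_flags)),
              all(names(religious_flags) %in% items))
  }
  structure(list(substance = substance, items = items,
                 religious_flags = religious_flags,
                 censor_visit = censor_visit,
                 control_visit = control_visit), class = "outcome_spec")
}

#' Default outcome specs matching the synthetic cohort's item columns
#'
#' Alcohol, nicotine, cannabis, and an "any substance" outcome defined as the
#' union of the three item sets plus the other-substance items.
#'
#' @return named list of [outcome_spec()] objects.
#' @export
default_outcome_specs <- function() {
  it <- cohort_item_sets()
  list(
    alcohol = outcome_spec("alcohol", it$alcohol,
                           c(su_alc_sip = "su_alc_sip_religious")),
    nicotine = outcome_spec("nicotine", it$nicotine,
                            c(su_nic_cig = "su_nic_cig_religious")),
    cannabis = outcome_spec("cannabis", it$cannabis),
    any = outcome_spec("any",
                       unlist(it, use.names = FALSE),
                       c(su_alc_sip = "su_alc_sip_religious",
                         su_nic_cig = "su_nic_cig_religious"))
  )
}

#' Harmonize annual and phone endorsement sources
#'
#' Stacks the two instruments, validates visit labels against the ordered
#' visit key, coerces endorsement responses to 0/1 (any other value, e.g.
#' refuse/don't-know codes, becomes missing) and sorts by participant and
#' chronological visit order.
#'
#' @param annual,phone long-format data frames with `id` and `visit` columns;
#'   `phone` may be `NULL` or empty.
#' @param item_cols columns to coerce to binary; defaults to all shared
#'   non-key columns.
#' @param visit_levels ordered visit labels (the visit-order key).
#' @return a single sorted long table with `visit` as an ordered factor level
#'   index column `visit_order` added.
#' @export
harmonize_sources <- function(annual, phone = NULL,
                              item_cols = NULL,
                              visit_levels = default_visit_levels()) {
  tabs <- Filter(function(t) !is.null(t) && nrow(t) > 0, list(annual, phone))
  stopifnot(length(tabs) >= 1)
  all_cols <- unique(unlist(lapply(tabs, names)))
  tabs <- lapply(tabs, function(t) {
    for (cc in setdiff(all_cols, names(t))) t[[cc]] <- NA
    t[all_cols]
  })
  out <- do.call(rbind, tabs)
  bad <- setdiff(unique(out$visit), visit_levels)
  if (length(bad)) {
    stop(sprintf("unknown visit label(s): %s", paste(bad, collapse = ", ")),
         call. = FALSE)
  }
  if (is.null(item_cols)) {
    item_cols <- setdiff(all_cols, c("id", "visit", "interview_age_months"))
    item_cols <- item_cols[vapply(out[item_cols], is.numeric, TRUE)]
  }
  for (cc in item_cols) {
    v <- out[[cc]]
    v[!(v %in% c(0, 1))] <- NA
    out[[cc]] <- v
  }
  out$visit_order <- match(out$visit, visit_levels)
  out <- out[order(out$id, out$visit_order), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Mask endorsements flagged as exclusively religious-context
#'
#' For each (item, flag) pair in the spec, endorsements (`item == 1`) whose
#' flag is set are recoded to missing before first-affirmative aggregation,
#' so religious or ceremonial exposure is not misclassified as initiation.
#'
#' @param table harmonized long table.
#' @param spec an [outcome_spec()].
#' @return the table with flagged endorsements set to `NA`.
#' @export
mask_religious_context <- function(table, spec) {
  for (item in names(spec$religious_flags)) {
    flag <- spec$religious_flags[[item]]
    if (!flag %in% names(table) || !item %in% names(table)) next
    hit <- !is.na(table[[item]]) & table[[item]] == 1 &
      !is.na(table[[flag]]) & table[[flag]] == 1
    table[[item]][hit] <- NA
  }
  table
}

#' Derive a time-to-initiation outcome per participant
#'
#' Scans each participant's harmonized, religious-masked endorsement history
#' in visit order through the censoring visit (FU4). The first visit with any
#' affirmative endorsement among the spec's items defines the event; time is
#' months since baseline at that visit. Missing endorsements are skipped, not
#' treated as 0. Non-initiators are censored at their last observed visit on
#' or before FU4; they are controls only if they were observed at the control
#' anchor visit (FU3), otherwise their case-control status is missing. A
#' baseline endorsement is retained as an event at `baseline_event_time`
#' months (default 0.5) so that follow-up has positive length.
#'
#' @param table harmonized long table containing the spec's item columns.
#' @param spec an [outcome_spec()].
#' @param tracking long table with `id`, `visit`, `interview_age_months`
#'   giving interview age per observed visit (defaults to `table` itself).
#' @param visit_levels ordered visit labels.
#' @param baseline_event_time months assigned to a baseline-visit event.
#' @return data frame with one row per participant: `id`, `time_months`,
#'   `event` (0/1), `status` (case/control/missing).
#' @export
derive_outcome <- function(table, spec, tracking = table,
                           visit_levels = default_visit_levels(),
                           baseline_event_time = 0.5) {
  table <- mask_religious_context(table, spec)
  items <- intersect(spec$items, names(table))
  if (!length(items)) stop("none of the spec's item columns are present")
  censor_ord <- match(spec$censor_visit, visit_levels)
  control_ord <- match(spec$control_visit, visit_levels)
  if (is.na(censor_ord)) stop("unknown censor visit label: ", spec$censor_visit)

  if (!"visit_order" %in% names(table)) {
    table$visit_order <- match(table$visit, visit_levels)
  }
  if (!"visit_order" %in% names(tracking)) {
    tracking$visit_order <- match(tracking$visit, visit_levels)
  }
  # age lookup: months since baseline per (id, visit)
  tr <- tracking[!is.na(tracking$visit_order) &
                   tracking$visit_order <= censor_ord,
                 c("id", "visit_order", "interview_age_months")]
  tr <- tr[order(tr$id, tr$visit_order), ]
  base_age <- tapply(tr$interview_age_months, tr$id,
                     function(x) x[1])
  # restrict endorsements to follow-up window
  tab <- table[!is.na(table$visit_order) & table$visit_order <= censor_ord, ,
               drop = FALSE]
  tab <- tab[order(tab$id, tab$visit_order), , drop = FALSE]

  ids <- unique(tr$id)
  n_dropped <- length(setdiff(unique(table$id), ids))
  if (n_dropped > 0) {
    message(sprintf("derive_outcome: %d participant(s) with no tracked visits excluded",
                    n_dropped))
  }

  any_pos <- rep(FALSE, nrow(tab))
  for (cc in items) {
    any_pos <- any_pos | (!is.na(tab[[cc]]) & tab[[cc]] == 1)
  }
  pos <- tab[any_pos, c("id", "visit_order")]
  first_pos <- if (nrow(pos)) tapply(pos$visit_order, pos$id, min) else
    stats::setNames(numeric(0), character(0))

  tr_by_id <- split(seq_len(nrow(tr)), tr$id)
  res <- lapply(ids, function(pid) {
    ix <- tr_by_id[[pid]]
    vo <- tr$visit_order[ix]
    age <- tr$interview_age_months[ix]
    b_age <- age[1]
    fp <- unname(first_pos[pid])
    if (!is.na(fp) && fp %in% vo) {
      # event: months since baseline at first affirmative visit
      t_ev <- age[match(fp, vo)] - b_age
      if (t_ev <= 0) t_ev <- baseline_event_time
      return(data.frame(id = pid, time_months = t_ev, event = 1L,
                        status = "case", stringsAsFactors = FALSE))
    }
    t_cens <- max(age) - b_age
    st <- if (!is.na(control_ord) && control_ord %in% vo) "control" else "missing"
    data.frame(id = pid, time_months = t_cens, event = 0L, status = st,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Derive all outcomes for a set of specs
#'
#' @param table harmonized long table.
#' @param specs named list of [outcome_spec()] objects.
#' @param ... passed to [derive_outcome()].
#' @return named list of per-outcome data frames.
#' @export
derive_outcomes <- function(table, specs = default_outcome_specs(), ...) {
  lapply(specs, function(sp) derive_outcome(table, sp, ...))
}
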