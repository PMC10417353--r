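#' Volumetric percent-change cutoffs for BT-RADS scoring
#'
#' Defaults follow the volumetric cutoffs used for automated structured
#' reporting: recurrence when the T2w/FLAIR lesion changes in volume by 100%
#' or more, or the enhancing CE-T1w lesion increases by 40% or more;
#' "worsened" when the enhancing lesion increases by 20% or more or the
#' FLAIR lesion by 50% or more. All comparisons are inclusive (">= cutoff").
#'
#' @param recurrence_flair_pct FLAIR change (in percent) meaning recurrence
#'   (default 100; by default a change in either direction of this magnitude
#'   triggers it — see `flair_recurrence_increase_only`).
#' @param recurrence_enh_pct enhancing increase meaning recurrence (40).
#' @param worsened_enh_pct enhancing increase meaning worsened (20).
#' @param worsened_flair_pct FLAIR increase meaning worsened (50).
#' @param post_rt_window_days window after RT completion in which worsening
#'   is attributed to treatment effect and scored 3a (default 90).
#' @param stability_band_pct band (percent) within which a change counts as
#'   stable (default 10).
#' @param min_measurable_cc volumes below this are treated as absent (0.1).
#' @param flair_recurrence_increase_only if TRUE, only FLAIR increases
#'   trigger the 100% recurrence rule.
#' @return object of class `cutoff_params`.
#' @export
cutoff_params <- function(recurrence_flair_pct = 100,
                          recurrence_enh_pct = 40,
                          worsened_enh_pct = 20,
                          worsened_flair_pct = 50,
                          post_rt_window_days = 90L,
                          stability_band_pct = 10,
                          min_measurable_cc = 0.1,
                          flair_recurrence_increase_only = FALSE) {
  if (worsened_enh_pct >= recurrence_enh_pct ||
      worsened_flair_pct >= recurrence_flair_pct)
    stop("worsened cutoffs must be below recurrence cutoffs", call. = FALSE)
  structure(list(recurrence_flair_pct = recurrence_flair_pct,
                 recurrence_enh_pct = recurrence_enh_pct,
                 worsened_enh_pct = worsened_enh_pct,
                 worsened_flair_pct = worsened_flair_pct,
                 post_rt_window_days = as.integer(post_rt_window_days),
                 stability_band_pct = stability_band_pct,
                 min_measurable_cc = min_measurable_cc,
                 flair_recurrence_increase_only = flair_recurrence_increase_only),
            class = "cutoff_params")
}

#' A longitudinal visit series
#'
#' @param date_days integer days since surgery, strictly increasing.
#' @param flair_cc T2w/FLAIR lesion (GTV1 segmentation) volume in cc.
#' @param enh_cc enhancing CE-T1w lesion volume (after cavity removal) in cc.
#' @param days_since_rt days since RT completion, or NA when unknown/not yet
#'   treated.
#' @param is_baseline logical; defaults to TRUE for the first visit only.
#' @return data.frame of class `visit_series`.
#' @export
visit_series <- function(date_days, flair_cc, enh_cc,
                         days_since_rt = NA_integer_, is_baseline = NULL) {
  n <- length(date_days)
  if (n < 1) stop("series must contain at least one visit", call. = FALSE)
  if (n > 1 && any(diff(date_days) <= 0))
    stop("visit dates must be strictly increasing", call. = FALSE)
  if (any(flair_cc < 0) || any(enh_cc < 0))
    stop("lesion volumes must be non-negative", call. = FALSE)
  if (is.null(is_baseline)) is_baseline <- seq_len(n) == 1L
  if (sum(is_baseline) > 1)
    stop("at most one baseline visit per series", call. = FALSE)
  structure(data.frame(date_days = as.integer(date_days),
                       flair_cc = as.numeric(flair_cc),
                       enh_cc = as.numeric(enh_cc),
                       days_since_rt = as.integer(rep_len(days_since_rt, n)),
                       is_baseline = as.logical(rep_len(is_baseline, n))),
            class = c("visit_series", "data.frame"))
}

#' Percent change in lesion volume between two visits
#'
#' `(curr - prev) / prev * 100` when the previous volume is measurable.
#' A lesion appearing from below the measurability floor is flagged
#' `new_lesion`; one disappearing below it is flagged `resolved`; two
#' sub-measurable volumes count as 0% change.
#'
#' @param prev_cc,curr_cc non-negative volumes in cc.
#' @param min_measurable_cc measurability floor in cc.
#' @return `list(pct, flag)` where `flag` is one of "none", "new_lesion",
#'   "resolved"; `pct` is NA when a flag fires.
#' @export
percent_change <- function(prev_cc, curr_cc, min_measurable_cc = 0.1) {
  if (prev_cc < 0 || curr_cc < 0)
    stop("volumes must be non-negative", call. = FALSE)
  prev_ok <- prev_cc >= min_measurable_cc
  curr_ok <- curr_cc >= min_measurable_cc
  if (prev_ok) {
    list(pct = (curr_cc - prev_cc) / prev_cc * 100,
         flag = if (!curr_ok) "resolved" else "none")
  } else if (curr_ok) {
    list(pct = NA_real_, flag = "new_lesion")
  } else {
    list(pct = 0, flag = "none")
  }
}

# Core decision tree for one visit. dflair/denh are percent_change() results
# relative to the previous visit; prev_worsened is the carried state.
score_one <- function(dflair, denh, days_since_rt, is_baseline, prev_worsened,
                      params) {
  rationale <- character(0)
  fire <- function(id) rationale <<- c(rationale, id)
  result <- function(major, sub = "none", worsened = FALSE) {
    structure(list(major = major, sub = sub, worsened_flag = worsened,
                   pct_flair = dflair$pct, pct_enh = denh$pct,
                   rationale = rationale), class = "score_result")
  }
  if (is_baseline) {
    fire("baseline")
    return(result(0L))
  }
  pf <- dflair$pct; pe <- denh$pct
  flair_rec <- !is.na(pf) &&
    (if (params$flair_recurrence_increase_only) pf >= params$recurrence_flair_pct
     else abs(pf) >= params$recurrence_flair_pct)
  enh_rec <- !is.na(pe) && pe >= params$recurrence_enh_pct
  new_lesion <- dflair$flag == "new_lesion" || denh$flag == "new_lesion"
  if (flair_rec || enh_rec || new_lesion) {
    if (flair_rec) fire("recurrence_flair_change")
    if (enh_rec) fire("recurrence_enh_increase")
    if (new_lesion) fire("new_lesion")
    return(result(4L))
  }
  worsened <- (!is.na(pe) && pe >= params$worsened_enh_pct) ||
    (!is.na(pf) && pf >= params$worsened_flair_pct)
  if (worsened) {
    if (!is.na(pe) && pe >= params$worsened_enh_pct) fire("worsened_enh")
    if (!is.na(pf) && pf >= params$worsened_flair_pct) fire("worsened_flair")
    if (isTRUE(prev_worsened)) {
      fire("consecutive_worsening")
      return(result(3L, "c", worsened = TRUE))
    }
    if (is.na(days_since_rt)) {
      warning("days_since_rt missing for a worsened visit; scoring 3b")
      fire("post_rt_unknown")
      return(result(3L, "b", worsened = TRUE))
    }
    if (days_since_rt <= params$post_rt_window_days) {
      fire("within_post_rt_window")
      return(result(3L, "a", worsened = TRUE))
    }
    fire("outside_post_rt_window")
    return(result(3L, "b", worsened = TRUE))
  }
  band <- params$stability_band_pct
  dec_f <- dflair$flag == "resolved" || (!is.na(pf) && pf <= -band)
  dec_e <- denh$flag == "resolved" || (!is.na(pe) && pe <= -band)
  inc_f <- !is.na(pf) && pf >= band
  inc_e <- !is.na(pe) && pe >= band
  if ((dec_f && inc_e) || (dec_e && inc_f)) {
    fire("mixed_findings")
    return(result(3L, "b"))
  }
  if (dec_f && dec_e) {
    fire("both_decreased")
    return(result(1L))
  }
  fire("stable")
  result(2L)
}

#' @export
print.score_result <- function(x, ...) {
  cat(sprintf("BT-RADS %s  (rules: %s)\n", format_score(x),
              paste(x$rationale, collapse = " -> ")))
  invisible(x)
}

#' Format a score result as the clinical code
#'
#' @param x a `score_result`.
#' @return e.g. "0", "2", "3a", "4".
#' @export
format_score <- function(x) {
  paste0(x$major, if (x$sub != "none") x$sub else "")
}

#' Classify the latest visit of a longitudinal series
#'
#' Applies the volumetric decision tree to the last visit of `history`,
#' carrying the worsened-state chain through the earlier visits. Rules, in
#' order: baseline visit scores 0; recurrence-level change (FLAIR changed by
#' >= 100%, enhancing increased by >= 40%, or a new measurable lesion)
#' scores 4; worsened imaging (enhancing +20% or FLAIR +50%, inclusive)
#' scores 3 — sub-grade c when the previous visit had already worsened below
#' the recurrence cutoff, a when within the post-RT window, b otherwise;
#' mixed findings (one measure decreased beyond the stability band while the
#' other increased beyond it) score the indeterminate 3b; both measures
#' decreased scores 1; anything else is stable, 2.
#'
#' @param history a [visit_series()] whose last row is the visit to score.
#' @param params a [cutoff_params()].
#' @return a `score_result`: major category 0-4, sub-letter a/b/c or
#'   "none", the worsened flag, percent changes, and the fired-rule trace.
#' @export
classify_visit <- function(history, params = cutoff_params()) {
  res <- classify_series(history, params)
  res[[length(res)]]
}

#' Classify every visit of a longitudinal series
#'
#' Sequential application of the decision tree; the only cross-visit state
#' is the worsened-flag chain that produces 3c on consecutive worsened
#' visits. Percent changes are referenced to the immediately preceding
#' visit.
#'
#' @inheritParams classify_visit
#' @param visits a [visit_series()] (or data.frame with its columns).
#' @return list of `score_result`, one per visit.
#' @export
classify_series <- function(visits, params = cutoff_params()) {
  if (is.data.frame(visits) && !inherits(visits, "visit_series"))
    visits <- visit_series(visits$date_days, visits$flair_cc, visits$enh_cc,
                           visits$days_since_rt,
                           if (!is.null(visits$is_baseline)) visits$is_baseline)
  stopifnot(inherits(visits, "visit_series"))
  n <- nrow(visits)
  if (n < 1) stop("empty visit series", call. = FALSE)
  out <- vector("list", n)
  prev_worsened <- FALSE
  for (i in seq_len(n)) {
    if (i == 1L) {
      dflair <- list(pct = NA_real_, flag = "none")
      denh <- dflair
    } else {
      dflair <- percent_change(visits$flair_cc[i - 1], visits$flair_cc[i],
                               params$min_measurable_cc)
      denh <- percent_change(visits$enh_cc[i - 1], visits$enh_cc[i],
                             params$min_measurable_cc)
    }
    out[[i]] <- score_one(dflair, denh, visits$days_since_rt[i],
                          visits$is_baseline[i], prev_worsened, params)
    prev_worsened <- out[[i]]$worsened_flag
  }
  out
}

#' Tabulate a classified series
#'
#' @param visits a [visit_series()].
#' @param results output of [classify_series()].
#' @return data.frame mirroring the series with score, sub, percent changes
#'   and rationale columns.
#' @export
score_table <- function(visits, results) {
  stopifnot(nrow(visits) == length(results))
  data.frame(
    visit_index = seq_len(nrow(visits)),
    date_days = visits$date_days,
    days_since_rt = visits$days_since_rt,
    flair_cc = visits$flair_cc,
    enh_cc = visits$enh_cc,
    pct_flair = vapply(results, function(r)
      if (is.null(r$pct_flair)) NA_real_ else as.numeric(r$pct_flair), 1),
    pct_enh = vapply(results, function(r)
      if (is.null(r$pct_enh)) NA_real_ else as.numeric(r$pct_enh), 1),
    score = vapply(results, format_score, ""),
    worsened = vapply(results, function(r) r$worsened_flag, TRUE),
    rationale = vapply(results, function(r)
      paste(r$rationale, collapse = ";"), ""))
}
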