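#' @keywords internal
OTHER_CATEGORIES <- c("other_treatment", "not_observable_in_line", "late_therapy",
                      "no_followup_diagnosis", "surgery_no_therapy",
                      "bronchoscopy_no_surgery_no_therapy", "none_of_the_above")

# Hierarchy used when several treatment groups are billed inside one line
# window: the published assignment is hierarchical in the table's listing
# order.
GROUP_PRIORITY <- c(Immunotherapy = 1L, Inhibitors = 2L, Chemotherapy = 3L,
                    Radiotherapy = 4L, Study = 5L)

#' Therapy-relevant events of one patient
#'
#' Matches the patient's dispensing/procedure events against the therapy
#' entries of the code table and returns them with their treatment-group and
#' cancer-type assignment. Study primary markers count only when a study
#' companion code is billed in the same quarter; companions themselves are
#' never therapy events.
#'
#' @param rec per-patient record.
#' @param codes a [load_code_table()] table.
#' @return data.frame: `date, system, code, setting, treatment_group,
#'   cancer_type`, ordered by date.
#' @export
therapy_events <- function(rec, codes) {
  ev <- rec$events
  ev <- ev[ev$kind %in% c("dispensing", "procedure"), , drop = FALSE]
  empty <- data.frame(date = as.Date(character(0)), system = character(0),
                      code = character(0), setting = character(0),
                      treatment_group = character(0), cancer_type = character(0))
  if (!nrow(ev)) return(empty)
  idx <- match_codes(codes, ev$system, ev$code)
  role <- ifelse(is.na(idx), NA_character_, codes$role[idx])
  grp <- ifelse(is.na(idx), "none", codes$treatment_group[idx])
  ct <- ifelse(is.na(idx), "none", codes$cancer_type[idx])

  keep <- !is.na(role) & role == "therapy"
  # study primaries: paired with a same-quarter companion
  prim <- !is.na(role) & role == "study_marker" & grp == "Study"
  comp <- !is.na(role) & role == "study_marker" & grp == "none"
  if (any(prim)) {
    comp_q <- unique(quarter_of(ev$date[comp]))
    keep <- keep | (prim & quarter_of(ev$date) %in% comp_q)
  }
  out <- data.frame(date = ev$date[keep], system = ev$system[keep],
                    code = ev$code[keep], setting = ev$setting[keep],
                    treatment_group = grp[keep], cancer_type = ct[keep])
  out <- out[order(out$date, out$system, out$code, method = "radix"), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Detect the first-line treatment episode
#'
#' First-line therapy is the treatment whose commencement is billed in the
#' index quarter or the following quarter: the earliest therapy-relevant
#' event there opens the episode, and all therapy events within the
#' collection window (default 30 days) belong to it.
#'
#' @inheritParams therapy_events
#' @param index_q index quarter ordinal.
#' @param window collection window length in days.
#' @return list with `start`, `window_end`, `events` (window events),
#'   `group`; or `NULL` when no therapy commences in the two quarters.
#' @export
detect_first_line <- function(rec, index_q, codes, window = 30L) {
  te <- therapy_events(rec, codes)
  lo <- quarter_start(index_q)
  hi <- quarter_end(quarter_shift(index_q, 1L))
  cand <- te[te$date >= lo & te$date <= hi, , drop = FALSE]
  if (!nrow(cand)) return(NULL)
  start <- min(cand$date)
  wend <- start + window
  win <- te[te$date >= start & te$date <= wend, , drop = FALSE]
  list(line = "first", start = start, window_end = wend, events = win,
       group = assign_group(win))
}

#' Hierarchical treatment-group assignment of a line episode
#'
#' The highest-priority treatment group billed inside the window wins:
#' Immunotherapy > Inhibitors > Chemotherapy > Radiotherapy > Study.
#'
#' @param events window events as returned inside [detect_first_line()].
#' @return treatment-group name, or `NA` for an empty window.
#' @export
assign_group <- function(events) {
  if (is.list(events) && !is.null(events$events)) events <- events$events
  grps <- unique(events$treatment_group)
  grps <- grps[grps %in% names(GROUP_PRIORITY)]
  if (!length(grps)) return(NA_character_)
  names(which.min(GROUP_PRIORITY[grps]))
}

#' Detect the second-line treatment episode
#'
#' Scanning therapy events dated more than one window length after the
#' first-line start, the first event whose billing code did not occur in the
#' first-line window opens the second-line episode (with its own window).
#' Re-entering the same treatment group with a different code is possible;
#' repeats of first-line codes never open a line.
#'
#' @inheritParams detect_first_line
#' @param first the first-line episode.
#' @return episode list as in [detect_first_line()], or `NULL`.
#' @export
detect_second_line <- function(rec, first, codes, window = 30L) {
  if (is.null(first)) return(NULL)
  te <- therapy_events(rec, codes)
  seen <- unique(paste(first$events$system, first$events$code))
  later <- te[te$date > first$start + window, , drop = FALSE]
  new <- later[!paste(later$system, later$code) %in% seen, , drop = FALSE]
  if (!nrow(new)) return(NULL)
  start <- min(new$date)
  wend <- start + window
  win <- te[te$date >= start & te$date <= wend, , drop = FALSE]
  list(line = "second", start = start, window_end = wend, events = win,
       group = assign_group(win))
}

#' Classify cancer type from line-of-therapy drugs
#'
#' Collects the NSCLC/SCLC tags of the therapy codes billed in the first-line
#' window. A uniform tag yields the call; mixed tags in the deciding window
#' yield `unclassifiable` with `conflicting = TRUE` (the published rule
#' demands unambiguous assignment); a window with only untyped codes falls
#' through to the second-line window. Patients with no typed code in either
#' window are unclassifiable.
#'
#' @param first,second line episodes (either may be `NULL`).
#' @return list with `call` (`"NSCLC"`, `"SCLC"`, `"unclassifiable"`),
#'   `basis` (`"first_line"`, `"second_line"`, `"none"`) and `conflicting`.
#' @export
classify_cancer_type <- function(first, second = NULL) {
  tags_of <- function(e) {
    if (is.null(e)) return(character(0))
    unique(e$events$cancer_type[e$events$cancer_type %in% CANCER_TYPES])
  }
  for (ln in list(list(e = first, basis = "first_line"),
                  list(e = second, basis = "second_line"))) {
    tg <- tags_of(ln$e)
    if (length(tg) == 1L)
      return(list(call = tg, basis = ln$basis, conflicting = FALSE))
    if (length(tg) > 1L)
      return(list(call = "unclassifiable", basis = ln$basis, conflicting = TRUE))
  }
  list(call = "unclassifiable", basis = "none", conflicting = FALSE)
}

#' Categorize a patient without a first-line episode
#'
#' Reproduces the published "other treatment" definition cascade, evaluated
#' in order: other treatment (inpatient medication-application marker OPS
#' 8-541 within one month of the index quarter), not observable in line (no
#' follow-up documentation at all), late therapy (therapy billed only after
#' the line windows), no follow-up diagnosis (lung cancer never re-coded
#' after the index quarter), surgical intervention without therapy,
#' bronchoscopy without surgery or therapy, and none of the above.
#'
#' @inheritParams detect_first_line
#' @return one of the category names in `OTHER_CATEGORIES`.
#' @export
categorize_untreated <- function(rec, index_q, codes, window = 30L) {
  ev <- rec$events
  idx <- match_codes(codes, ev$system, ev$code)
  role <- ifelse(is.na(idx), NA_character_, codes$role[idx])
  q <- quarter_of(ev$date)
  q_end <- quarter_end(index_q)

  marker <- !is.na(role) & role == "inpatient_chemo_marker" &
    ev$date >= quarter_start(index_q) & ev$date <= q_end + window
  if (any(marker)) return("other_treatment")

  if (!any(ev$date > q_end)) return("not_observable_in_line")

  te <- therapy_events(rec, codes)
  if (nrow(te) && any(te$date > quarter_end(quarter_shift(index_q, 1L))))
    return("late_therapy")

  lc_later <- is_lc_dx(ev) & ev$date > q_end
  if (!any(lc_later)) return("no_followup_diagnosis")

  obs <- q >= index_q & q <= quarter_shift(index_q, 1L)
  if (any(!is.na(role) & role == "surgery" & obs)) return("surgery_no_therapy")
  if (any(!is.na(role) & role == "bronchoscopy" & obs)) return("bronchoscopy_no_surgery_no_therapy")
  "none_of_the_above"
}

#' Construct treatment lines and cancer-type calls for a cohort
#'
#' Runs first-/second-line detection, hierarchical group assignment, the
#' untreated cascade and drug-based cancer-type classification for every
#' included patient of a selection.
#'
#' @param claims a [claims_data()] object.
#' @param selection output of [select_cohort()].
#' @param codes a [load_code_table()] table.
#' @param window line collection window in days (default 30; the published
#'   "one month").
#' @return list of data.frames: `lines` (`patient_id, line, start, window_end,
#'   group`), `types` (`patient_id, call, basis, conflicting`) and `labels`
#'   (`patient_id, first_line_label` -- a treatment group or an
#'   other-treatment category, exactly one per included patient).
#' @export
build_lines <- function(claims, selection, codes = load_code_table(), window = 30L) {
  inc <- selection[selection$status == "included", , drop = FALSE]
  recs <- split_records(claims, inc$patient_id)
  lines <- list(); types <- list(); labels <- list()
  for (i in seq_len(nrow(inc))) {
    pid <- inc$patient_id[i]
    iq <- quarter_parse(inc$index_quarter[i])
    rec <- recs[[pid]]
    fl <- detect_first_line(rec, iq, codes, window)
    sl <- detect_second_line(rec, fl, codes, window)
    if (!is.null(fl) && is.na(fl$group)) fl <- NULL  # defensive; window always has >=1 event
    ep <- Filter(Negate(is.null), list(fl, sl))
    if (length(ep))
      lines[[pid]] <- data.frame(
        patient_id = pid,
        line = vapply(ep, `[[`, "", "line"),
        start = as.Date(vapply(ep, function(e) format(e$start), "")),
        window_end = as.Date(vapply(ep, function(e) format(e$window_end), "")),
        group = vapply(ep, `[[`, "", "group"))
    ct <- classify_cancer_type(fl, sl)
    types[[pid]] <- data.frame(patient_id = pid, call = ct$call, basis = ct$basis,
                               conflicting = ct$conflicting)
    lab <- if (!is.null(fl)) fl$group else categorize_untreated(rec, iq, codes, window)
    labels[[pid]] <- data.frame(patient_id = pid, first_line_label = lab)
  }
  bind <- function(x, proto) if (length(x)) do.call(rbind, unname(x)) else proto
  list(
    lines = bind(lines, data.frame(patient_id = character(0), line = character(0),
                                   start = as.Date(character(0)),
                                   window_end = as.Date(character(0)), group = character(0))),
    types = bind(types, data.frame(patient_id = character(0), call = character(0),
                                   basis = character(0), conflicting = logical(0))),
    labels = bind(labels, data.frame(patient_id = character(0), first_line_label = character(0))))
}
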