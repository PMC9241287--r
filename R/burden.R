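#' @keywords internal
BURDEN_METRICS <- c("pharmacy_visits", "gp_visits", "specialist_visits",
                    "inpatient_days", "outpatient_hospital_treatments")

#' Burden-analysis eligibility
#'
#' The time-expenditure analysis is restricted to patients with exactly a
#' first-line therapy: patients with second-line therapy, without any
#' first-line therapy, not observable in line, or whose lung cancer was not
#' coded in outpatient care in at least two different quarters are excluded.
#'
#' @param rec per-patient record.
#' @param has_first,has_second does the patient have a first/second-line
#'   episode?
#' @param obs_end observation horizon for the outpatient M2Q check.
#' @return TRUE/FALSE.
#' @export
burden_eligible <- function(rec, has_first, has_second,
                            obs_end = as.Date("2018-12-31")) {
  if (!has_first || has_second) return(FALSE)
  outpatient_m2q(rec, obs_end)
}

#' Per-quarter time-expenditure series of one patient
#'
#' For relative quarters -4 .. +8 around the index quarter: pharmacy visits
#' (distinct dispensing dates), primary-care and specialist visits (distinct
#' date-provider contacts), inpatient hospital days (calendar days of
#' inpatient stays falling in the quarter, closed intervals) and outpatient
#' hospital treatments (hospital contacts in the outpatient setting).
#' Quarters with no enrollment overlap are reported as missing (`NA`), not
#' zero.
#'
#' @inheritParams burden_eligible
#' @param index_q index quarter ordinal.
#' @return data.frame with 13 rows: `relative_quarter` plus one column per
#'   metric.
#' @export
compute_burden <- function(rec, index_q) {
  ev <- rec$events
  merged <- merge_intervals(rec$enrollment)
  inpat <- rec$stays[rec$stays$mode == "inpatient", , drop = FALSE]
  rows <- lapply(-4:8, function(r) {
    qo <- quarter_shift(index_q, r)
    qs <- quarter_start(qo); qe <- quarter_end(qo)
    observed <- nrow(merged) && any(merged$start <= qe & merged$end >= qs)
    if (!observed)
      return(data.frame(relative_quarter = r, pharmacy_visits = NA_integer_,
                        gp_visits = NA_integer_, specialist_visits = NA_integer_,
                        inpatient_days = NA_integer_,
                        outpatient_hospital_treatments = NA_integer_))
    in_q <- ev$date >= qs & ev$date <= qe
    disp <- ev[in_q & ev$kind == "dispensing", , drop = FALSE]
    cont <- ev[in_q & ev$kind == "contact", , drop = FALSE]
    gp <- cont[cont$provider == "primary_care", , drop = FALSE]
    sp <- cont[cont$provider %in% SPECIALIST_PROVIDERS, , drop = FALSE]
    oh <- cont[cont$provider == "hospital" & cont$setting == "outpatient", , drop = FALSE]
    data.frame(
      relative_quarter = r,
      pharmacy_visits = length(unique(disp$date)),
      gp_visits = nrow(unique(gp[c("date", "provider")])),
      specialist_visits = nrow(unique(sp[c("date", "provider")])),
      inpatient_days = stay_days_in_quarter(inpat, qo),
      outpatient_hospital_treatments = nrow(oh))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Burden series for a cohort
#'
#' Applies [burden_eligible()] and [compute_burden()] to every included
#' patient and returns the per-patient series in long-ready wide format.
#'
#' @param claims a [claims_data()] object.
#' @param selection output of [select_cohort()].
#' @param lines output of [build_lines()].
#' @param obs_end observation horizon for the outpatient M2Q check.
#' @return data.frame: `patient_id, relative_quarter`, one column per metric;
#'   only burden-eligible patients appear.
#' @export
build_burden <- function(claims, selection, lines, obs_end = as.Date("2018-12-31")) {
  inc <- selection[selection$status == "included", , drop = FALSE]
  recs <- split_records(claims, inc$patient_id)
  ln <- lines$lines
  rows <- lapply(seq_len(nrow(inc)), function(i) {
    pid <- inc$patient_id[i]
    pl <- ln[ln$patient_id == pid, , drop = FALSE]
    rec <- recs[[pid]]
    if (!burden_eligible(rec, any(pl$line == "first"), any(pl$line == "second"), obs_end))
      return(NULL)
    b <- compute_burden(rec, quarter_parse(inc$index_quarter[i]))
    cbind(patient_id = pid, b)
  })
  out <- do.call(rbind, Filter(Negate(is.null), rows))
  if (is.null(out))
    out <- cbind(data.frame(patient_id = character(0)),
                 stats::setNames(as.data.frame(matrix(integer(0), 0, 6)),
                                 c("relative_quarter", BURDEN_METRICS)))
  rownames(out) <- NULL
  out
}

#' Aggregate burden series over strata
#'
#' Arithmetic mean of each metric per relative quarter within each stratum;
#' missing (unobserved) quarters are excluded from the denominator, so
#' partial follow-up reduces `n` instead of biasing the mean towards zero.
#' Empty strata are omitted with a warning.
#'
#' @param burden output of [build_burden()].
#' @param strata data.frame `patient_id, stratum` (e.g. cancer-type call, or
#'   type x region).
#' @return long-format data.frame: `stratum, metric, relative_quarter, mean, n`.
#' @export
aggregate_burden <- function(burden, strata) {
  m <- merge(burden, strata, by = "patient_id")
  lost <- setdiff(unique(strata$stratum), unique(m$stratum))
  if (length(lost)) warning("empty burden stratum/strata omitted: ",
                            paste(sort(lost), collapse = ", "))
  if (!nrow(m))
    return(data.frame(stratum = character(0), metric = character(0),
                      relative_quarter = integer(0), mean = numeric(0), n = integer(0)))
  rows <- list()
  for (met in BURDEN_METRICS) {
    agg_m <- stats::aggregate(m[[met]],
                              by = list(stratum = m$stratum, relative_quarter = m$relative_quarter),
                              FUN = function(v) mean(v, na.rm = TRUE))
    agg_n <- stats::aggregate(m[[met]],
                              by = list(stratum = m$stratum, relative_quarter = m$relative_quarter),
                              FUN = function(v) sum(!is.na(v)))
    rows[[met]] <- data.frame(stratum = agg_m$stratum, metric = met,
                              relative_quarter = agg_m$relative_quarter,
                              mean = ifelse(agg_n$x > 0L, agg_m$x, NA_real_),
                              n = agg_n$x)
  }
  out <- do.call(rbind, rows)
  out <- out[order(out$stratum, out$metric, out$relative_quarter, method = "radix"), , drop = FALSE]
  rownames(out) <- NULL
  out
}
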