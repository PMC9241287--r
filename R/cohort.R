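#' @keywords internal
EXCLUSION_REASONS <- c("not_confirmed", "prior_lc_diagnosis", "insufficient_pre_observation",
                       "other_primary_tumor", "insufficient_post_observation")

# ICD-10 three-character root of a canonical diagnosis code
icd_root <- function(code) substr(code, 1L, 3L)

is_lc_dx <- function(ev) {
  ev$kind == "diagnosis" & icd_root(ev$code) %in% c("C33", "C34")
}

# Other primary solid tumour: C00-C75 without C33, C34, C44, C61
is_other_primary_dx <- function(ev) {
  root <- icd_root(ev$code)
  ev$kind == "diagnosis" &
    grepl("^C[0-9]{2}", root) & root >= "C00" & root <= "C75" &
    !root %in% c("C33", "C34", "C44", "C61")
}

#' Find the index quarter of a patient
#'
#' The index quarter is the earliest calendar quarter within the study period
#' that contains a lung-cancer (C33/C34) diagnosis event; `NA` if there is
#' none.
#'
#' @param rec per-patient record (see [select_cohort()] for the batch
#'   interface; a record is a list with `patient`, `enrollment`, `events`,
#'   `stays` slices).
#' @param period length-2 `Date` vector: first and last day of the index
#'   period (default 2015-01-01 .. 2016-12-31).
#' @return integer quarter ordinal or `NA`.
#' @export
find_index_quarter <- function(rec, period = as.Date(c("2015-01-01", "2016-12-31"))) {
  ev <- rec$events
  lc <- ev[is_lc_dx(ev) & ev$date >= period[1L] & ev$date <= period[2L], , drop = FALSE]
  if (!nrow(lc)) return(NA_integer_)
  min(quarter_of(lc$date))
}

#' Washout: is the lung-cancer diagnosis incident?
#'
#' TRUE iff no C33/C34 diagnosis event falls in the eight quarters before the
#' index quarter (quarters index-8 .. index-1).
#'
#' @inheritParams find_index_quarter
#' @param index_q index quarter ordinal.
#' @export
is_newly_diagnosed <- function(rec, index_q) {
  ev <- rec$events
  lc <- ev[is_lc_dx(ev), , drop = FALSE]
  if (!nrow(lc)) return(TRUE)
  q <- quarter_of(lc$date)
  !any(q >= quarter_shift(index_q, -8L) & q <= quarter_shift(index_q, -1L))
}

#' Diagnosis confirmation (M2Q or confirmed inpatient coding)
#'
#' TRUE iff the lung-cancer diagnosis was coded in outpatient care in at least
#' two different quarters of the observation period (M2Q criterion), or at
#' least once as a confirmed diagnosis during inpatient treatment. The
#' outpatient branch deliberately ignores the `confirmed` flag; the inpatient
#' branch requires it.
#'
#' @inheritParams is_newly_diagnosed
#' @param obs_end last day of the observation period used for M2Q counting
#'   (default: whole data horizon, 2018-12-31).
#' @export
confirm_diagnosis <- function(rec, index_q, obs_end = as.Date("2018-12-31")) {
  ev <- rec$events
  lc <- ev[is_lc_dx(ev) & ev$date <= obs_end, , drop = FALSE]
  if (!nrow(lc)) return(FALSE)
  out_q <- unique(quarter_of(lc$date[lc$setting == "outpatient"]))
  if (length(out_q) >= 2L) return(TRUE)
  any(lc$setting == "inpatient" & lc$confirmed)
}

# TRUE iff the outpatient-only M2Q branch holds (used by burden eligibility,
# which the publication restricts to outpatient-confirmed patients).
outpatient_m2q <- function(rec, obs_end = as.Date("2018-12-31")) {
  ev <- rec$events
  lc <- ev[is_lc_dx(ev) & ev$setting == "outpatient" & ev$date <= obs_end, , drop = FALSE]
  length(unique(quarter_of(lc$date))) >= 2L
}

#' Apply the exclusion cascade to one candidate
#'
#' Checks, in fixed order: diagnosis confirmation, washout (prior lung-cancer
#' coding), eight quarters of continuous pre-observation enrollment, other
#' primary solid tumours (C00-C75 without C33/C34/C44/C61) within +/- 8
#' quarters of the index quarter, and post-observation time (enrollment must
#' reach the quarter after the index quarter). A patient failing several
#' checks is recorded with the first failing reason, so exclusion counts are
#' disjoint.
#'
#' @inheritParams confirm_diagnosis
#' @return list with `status` ("included"/"excluded") and `exclusion_reason`.
#' @export
apply_exclusions <- function(rec, index_q, obs_end = as.Date("2018-12-31")) {
  excl <- function(reason) list(status = "excluded", exclusion_reason = reason)
  if (!confirm_diagnosis(rec, index_q, obs_end)) return(excl("not_confirmed"))
  if (!is_newly_diagnosed(rec, index_q)) return(excl("prior_lc_diagnosis"))

  merged <- merge_intervals(rec$enrollment)
  pre_lo <- quarter_start(quarter_shift(index_q, -8L))
  pre_hi <- quarter_end(quarter_shift(index_q, -1L))
  covered <- nrow(merged) &&
    any(merged$start <= pre_lo & merged$end >= pre_hi)
  if (!covered) return(excl("insufficient_pre_observation"))

  ev <- rec$events
  op <- ev[is_other_primary_dx(ev), , drop = FALSE]
  if (nrow(op)) {
    q <- quarter_of(op$date)
    if (any(abs(q - index_q) <= 8L)) return(excl("other_primary_tumor"))
  }

  post_start <- quarter_start(quarter_shift(index_q, 1L))
  if (!nrow(merged) || max(merged$end) < post_start)
    return(excl("insufficient_post_observation"))

  list(status = "included", exclusion_reason = "none")
}

#' Metastasis-stage cohort of an included patient
#'
#' Based on secondary-neoplasm codes in the index quarter: C78/C79 (distant
#' metastases, clinical stage IV) dominates C77 (lymph-node metastases),
#' which dominates no metastasis coding.
#'
#' @inheritParams is_newly_diagnosed
#' @return one of `"distant_mets"`, `"lymph_node_mets"`, `"no_mets"`.
#' @export
assign_stage <- function(rec, index_q) {
  ev <- rec$events
  dx <- ev[ev$kind == "diagnosis" & quarter_of(ev$date) == index_q, , drop = FALSE]
  root <- icd_root(dx$code)
  if (any(root %in% c("C78", "C79"))) return("distant_mets")
  if (any(root == "C77")) return("lymph_node_mets")
  "no_mets"
}

#' Demographic strata at the index quarter
#'
#' Age at index = index year minus birth year, grouped into `<=60` vs `>60`
#' (unknown when the birth year is missing); gender and urban/rural region are
#' taken from the demographics table.
#'
#' @inheritParams is_newly_diagnosed
#' @return list with `age`, `age_group`, `gender`, `region`.
#' @export
stratify_demographics <- function(rec, index_q) {
  by <- rec$patient$birth_year[1L]
  if (is.null(by) || length(by) == 0L || is.na(by)) {
    age <- NA_integer_; grp <- "unknown"
  } else {
    age <- quarter_year(index_q) - by
    grp <- if (age <= 60L) "<=60" else ">60"
  }
  list(age = age, age_group = grp,
       gender = if (nrow(rec$patient)) rec$patient$gender[1L] else NA_character_,
       region = if (nrow(rec$patient)) rec$patient$municipality[1L] else NA_character_)
}

#' Select the incident lung-cancer cohort
#'
#' Runs index-quarter detection, confirmation, the exclusion cascade, stage
#' cohorting and demographic stratification for every patient. Patients with
#' no C33/C34 diagnosis in the index period are not candidates and are
#' reported with status `"no_index"`.
#'
#' @param claims a [claims_data()] object.
#' @param period index period (first/last day), default 2015--2016.
#' @param obs_end end of the observation horizon for confirmation.
#' @return data.frame with one row per patient: `patient_id, status,
#'   exclusion_reason, index_quarter` (label), `stage, age, age_group, gender,
#'   region`.
#' @export
select_cohort <- function(claims, period = as.Date(c("2015-01-01", "2016-12-31")),
                          obs_end = as.Date("2018-12-31")) {
  ids <- claims$patients$patient_id
  recs <- split_records(claims, ids)
  rows <- lapply(recs, function(rec) {
    iq <- find_index_quarter(rec, period)
    if (is.na(iq))
      return(data.frame(patient_id = rec$patient$patient_id[1L], status = "no_index",
                        exclusion_reason = "none", index_quarter = NA_character_,
                        stage = NA_character_, age = NA_integer_,
                        age_group = NA_character_, gender = NA_character_,
                        region = NA_character_))
    sel <- apply_exclusions(rec, iq, obs_end)
    if (sel$status == "included") {
      stage <- assign_stage(rec, iq)
      dem <- stratify_demographics(rec, iq)
    } else {
      stage <- NA_character_
      dem <- list(age = NA_integer_, age_group = NA_character_,
                  gender = NA_character_, region = NA_character_)
    }
    data.frame(patient_id = rec$patient$patient_id[1L], status = sel$status,
               exclusion_reason = sel$exclusion_reason,
               index_quarter = quarter_label(iq), stage = stage,
               age = dem$age, age_group = dem$age_group,
               gender = dem$gender, region = dem$region)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
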