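#' @keywords internal
EVENT_KINDS <- c("diagnosis", "dispensing", "procedure", "contact")
#' @keywords internal
SETTINGS <- c("inpatient", "outpatient", "none")
#' @keywords internal
PROVIDERS <- c("hospital", "oncologist", "pulmonologist", "radiologist", "internist",
               "primary_care", "other_office_based", "pharmacy", "unknown")
#' @keywords internal
SPECIALIST_PROVIDERS <- c("oncologist", "pulmonologist", "radiologist", "internist",
                          "other_office_based")

#' Assemble a claims dataset
#'
#' Bundles the four longitudinal SHI event tables into one validated object:
#' demographics (`patients`), insurance coverage intervals (`enrollment`),
#' billed events -- diagnoses, drug dispensings, procedures, physician
#' contacts -- (`events`) and hospital stays (`stays`). Events are sorted by
#' patient, date and kind; events dated outside all enrollment intervals are
#' kept but flagged in the logical column `in_enrollment`.
#'
#' @param patients data.frame: `patient_id, birth_year, gender, municipality`.
#' @param enrollment data.frame: `patient_id, start, end` (Dates).
#' @param events data.frame:
#'   `patient_id, date, kind, system, code, setting, provider, confirmed`.
#' @param stays data.frame: `patient_id, admission, discharge, mode`.
#' @return object of class `claims_data`.
#' @export
claims_data <- function(patients, enrollment, events, stays) {
  stopifnot(is.data.frame(patients), is.data.frame(enrollment),
            is.data.frame(events), is.data.frame(stays))
  patients$patient_id <- as.character(patients$patient_id)
  patients$birth_year <- as.integer(patients$birth_year)
  enrollment$patient_id <- as.character(enrollment$patient_id)
  enrollment$start <- as.Date(enrollment$start)
  enrollment$end <- as.Date(enrollment$end)
  if (any(enrollment$end < enrollment$start)) stop("enrollment interval with end < start")
  events$patient_id <- as.character(events$patient_id)
  events$date <- as.Date(events$date)
  if (nrow(events)) {
    bad <- !events$kind %in% EVENT_KINDS
    if (any(bad)) stop("unknown event kind: ", paste(unique(events$kind[bad]), collapse = ", "))
    if (any(events$kind == "dispensing" & events$system != "ATC"))
      stop("dispensing events must carry ATC codes")
    if (any(events$kind == "diagnosis" & events$system != "ICD10GM"))
      stop("diagnosis events must carry ICD10GM codes")
    has_code <- !is.na(events$code) & nzchar(events$code)
    events$code[has_code] <- normalize_code("OPS", events$code[has_code])
    events$confirmed <- as.logical(events$confirmed)
    events$confirmed[is.na(events$confirmed)] <- FALSE
  } else {
    events$confirmed <- logical(0)
  }
  stays$patient_id <- as.character(stays$patient_id)
  stays$admission <- as.Date(stays$admission)
  stays$discharge <- as.Date(stays$discharge)
  if (any(stays$discharge < stays$admission)) stop("hospital stay with discharge < admission")

  o <- order(events$patient_id, events$date, events$kind, events$system,
             events$code, method = "radix")
  events <- events[o, , drop = FALSE]
  rownames(events) <- NULL
  events$in_enrollment <- in_any_interval(events$patient_id, events$date, enrollment)
  patients <- patients[order(patients$patient_id, method = "radix"), , drop = FALSE]
  rownames(patients) <- NULL
  enrollment <- enrollment[order(enrollment$patient_id, enrollment$start, method = "radix"), , drop = FALSE]
  rownames(enrollment) <- NULL
  stays <- stays[order(stays$patient_id, stays$admission, stays$discharge, method = "radix"), , drop = FALSE]
  rownames(stays) <- NULL

  structure(list(patients = patients, enrollment = enrollment,
                 events = events, stays = stays),
            class = "claims_data")
}

in_any_interval <- function(ids, dates, enrollment) {
  if (!length(ids)) return(logical(0))
  enr <- split(enrollment[c("start", "end")], enrollment$patient_id)
  mapply(function(id, d) {
    e <- enr[[id]]
    !is.null(e) && any(d >= e$start & d <= e$end)
  }, ids, dates, USE.NAMES = FALSE)
}

#' @export
print.claims_data <- function(x, ...) {
  cat("SHI claims dataset:", nrow(x$patients), "patients,",
      nrow(x$events), "events,", nrow(x$stays), "hospital stays\n")
  invisible(x)
}

EVENT_COLS <- c("patient_id", "date", "kind", "system", "code", "setting", "provider", "confirmed")

#' Read a claims dataset from delimited text files
#'
#' Expects `patients.csv`, `enrollment.csv`, `events.csv` and `stays.csv` in
#' `dir` (UTF-8, comma-delimited, header row mandatory; the dialect written by
#' [write_claims()]). Unparseable dates are collected and reported with file
#' and line numbers rather than silently dropped.
#'
#' @param dir directory containing the four CSV files.
#' @return a [claims_data()] object.
#' @export
read_claims <- function(dir) {
  rd <- function(file, cols) {
    path <- file.path(dir, file)
    if (!file.exists(path)) stop("missing input file: ", path)
    x <- utils::read.csv(path, colClasses = "character", fileEncoding = "UTF-8")
    miss <- setdiff(cols, names(x))
    if (length(miss)) stop("schema error in ", file, ": missing column(s) ",
                           paste(miss, collapse = ", "))
    x[cols]
  }
  parse_dates <- function(x, file, col) {
    d <- as.Date(x[[col]], format = "%Y-%m-%d")
    bad <- which(is.na(d) & !is.na(x[[col]]) & nzchar(x[[col]]))
    if (length(bad)) stop("row error in ", file, ": unparseable ", col,
                          " at data line(s) ", paste(bad, collapse = ", "))
    d
  }
  patients <- rd("patients.csv", c("patient_id", "birth_year", "gender", "municipality"))
  patients$birth_year <- suppressWarnings(as.integer(patients$birth_year))
  enrollment <- rd("enrollment.csv", c("patient_id", "start", "end"))
  enrollment$start <- parse_dates(enrollment, "enrollment.csv", "start")
  enrollment$end <- parse_dates(enrollment, "enrollment.csv", "end")
  events <- rd("events.csv", EVENT_COLS)
  events$date <- parse_dates(events, "events.csv", "date")
  events$confirmed <- events$confirmed == "TRUE"
  stays <- rd("stays.csv", c("patient_id", "admission", "discharge", "mode"))
  stays$admission <- parse_dates(stays, "stays.csv", "admission")
  stays$discharge <- parse_dates(stays, "stays.csv", "discharge")
  claims_data(patients, enrollment, events, stays)
}

#' Write a claims dataset to delimited text files
#'
#' Inverse of [read_claims()]. Column and row order are deterministic
#' (patient_id, date, kind) so identical inputs produce byte-identical files.
#'
#' @param claims a [claims_data()] object.
#' @param dir output directory (created if absent).
#' @return invisibly, the paths written.
#' @export
write_claims <- function(claims, dir) {
  stopifnot(inherits(claims, "claims_data"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  wr <- function(x, file) {
    for (col in names(x)) if (inherits(x[[col]], "Date")) x[[col]] <- format(x[[col]], "%Y-%m-%d")
    path <- file.path(dir, file)
    utils::write.csv(x, path, row.names = FALSE, quote = FALSE, na = "", fileEncoding = "UTF-8")
    path
  }
  ev <- claims$events[EVENT_COLS]
  paths <- c(wr(claims$patients, "patients.csv"),
             wr(claims$enrollment, "enrollment.csv"),
             wr(ev, "events.csv"),
             wr(claims$stays, "stays.csv"))
  invisible(paths)
}

# Per-patient view used by the per-patient rule functions: a list with the
# demographics row, enrollment / events / stays slices for one insured person.
patient_record <- function(claims, id) {
  list(patient = claims$patients[claims$patients$patient_id == id, , drop = FALSE],
       enrollment = claims$enrollment[claims$enrollment$patient_id == id, , drop = FALSE],
       events = claims$events[claims$events$patient_id == id, , drop = FALSE],
       stays = claims$stays[claims$stays$patient_id == id, , drop = FALSE])
}

# Split a claims_data object into the per-patient records for all (or the
# given) patients at once; much faster than repeated subsetting.
split_records <- function(claims, ids = claims$patients$patient_id) {
  evs <- split(claims$events, factor(claims$events$patient_id, levels = ids))
  enr <- split(claims$enrollment, factor(claims$enrollment$patient_id, levels = ids))
  sty <- split(claims$stays, factor(claims$stays$patient_id, levels = ids))
  pts <- split(claims$patients, factor(claims$patients$patient_id, levels = ids))
  lapply(stats::setNames(seq_along(ids), ids), function(i)
    list(patient = pts[[i]], enrollment = enr[[i]], events = evs[[i]], stays = sty[[i]]))
}

# Merge enrollment intervals, tolerating gaps of < 1 day (i.e. adjacent
# intervals join). Returns a data.frame with start/end Dates.
merge_intervals <- function(enr) {
  if (!nrow(enr)) return(enr[c("start", "end")])
  enr <- enr[order(enr$start, enr$end), , drop = FALSE]
  start <- enr$start[1L]; end <- enr$end[1L]
  out_s <- out_e <- as.Date(character(0))
  for (i in seq_len(nrow(enr))[-1L]) {
    if (enr$start[i] <= end + 1L) {
      end <- max(end, enr$end[i])
    } else {
      out_s <- c(out_s, start); out_e <- c(out_e, end)
      start <- enr$start[i]; end <- enr$end[i]
    }
  }
  data.frame(start = c(out_s, start), end = c(out_e, end))
}

# Calendar days of an inpatient stay falling inside a quarter; closed
# interval, so admission and discharge days both count.
stay_days_in_quarter <- function(stays, qo) {
  if (!nrow(stays)) return(0L)
  qs <- quarter_start(qo); qe <- quarter_end(qo)
  lo <- pmax(stays$admission, qs)
  hi <- pmin(stays$discharge, qe)
  sum(pmax(0L, as.integer(hi - lo) + 1L))
}
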