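# Builders for small hand-made patients -------------------------------------

ev_dx <- function(date, code = "C34", setting = "outpatient",
                  provider = "pulmonologist", confirmed = FALSE)
  data.frame(date = as.Date(date), kind = "diagnosis", system = "ICD10GM",
             code = code, setting = setting, provider = provider, confirmed = confirmed)

ev_rx <- function(date, atc)
  data.frame(date = as.Date(date), kind = "dispensing", system = "ATC",
             code = atc, setting = "none", provider = "pharmacy", confirmed = FALSE)

ev_px <- function(date, system, code, setting = "outpatient", provider = "pulmonologist")
  data.frame(date = as.Date(date), kind = "procedure", system = system,
             code = code, setting = setting, provider = provider, confirmed = FALSE)

ev_ct <- function(date, provider = "primary_care", setting = "outpatient")
  data.frame(date = as.Date(date), kind = "contact", system = "",
             code = "", setting = setting, provider = provider, confirmed = FALSE)

# single-patient claims record (already in per-patient record form)
mk_rec <- function(events = NULL, stays = NULL,
                   enr_start = "2013-01-01", enr_end = "2018-12-31",
                   birth_year = 1950L, gender = "male", municipality = "urban",
                   pid = "T1") {
  events <- if (is.null(events))
    data.frame(patient_id = character(0), date = as.Date(character(0)),
               kind = character(0), system = character(0), code = character(0),
               setting = character(0), provider = character(0), confirmed = logical(0))
  else cbind(patient_id = pid, do.call(rbind, events))
  stays <- if (is.null(stays)) data.frame(patient_id = character(0),
                                          admission = as.Date(character(0)),
                                          discharge = as.Date(character(0)),
                                          mode = character(0))
           else cbind(patient_id = pid, do.call(rbind, stays))
  claims <- claims_data(
    data.frame(patient_id = pid, birth_year = birth_year, gender = gender,
               municipality = municipality),
    data.frame(patient_id = pid, start = as.Date(enr_start), end = as.Date(enr_end)),
    events, stays)
  list(patient = claims$patients, enrollment = claims$enrollment,
       events = claims$events, stays = claims$stays, claims = claims)
}

mk_stay <- function(adm, dis, mode = "inpatient")
  data.frame(admission = as.Date(adm), discharge = as.Date(dis), mode = mode)

# Independent brute-force oracle for the line-of-therapy window rules --------
# Deliberately naive: per-entry loops for code matching, a day-by-day scan for
# line starts, and an if-chain for the group hierarchy. Shares only the code
# table *data* with the implementation, none of its code paths.

oracle_entry_for <- function(codes, system, code) {
  for (j in seq_len(nrow(codes)))
    if (codes$system[j] == system && codes$code[j] == code) return(j)
  best <- NA_integer_; bestlen <- -1L
  for (j in seq_len(nrow(codes))) {
    if (codes$system[j] != system) next
    pre <- codes$is_prefix[j] || (system == "ICD10GM" && nchar(codes$code[j]) == 3L)
    if (!pre) next
    p <- codes$code[j]
    if (nchar(code) >= nchar(p) && substr(code, 1L, nchar(p)) == p && nchar(p) > bestlen) {
      best <- j; bestlen <- nchar(p)
    }
  }
  best
}

oracle_therapy_events <- function(rec, codes) {
  ev <- rec$events
  out <- NULL
  study_primary_q <- c(); companion_q <- c()
  rows <- list()
  for (i in seq_len(nrow(ev))) {
    if (!ev$kind[i] %in% c("dispensing", "procedure")) next
    j <- oracle_entry_for(codes, ev$system[i], ev$code[i])
    if (is.na(j)) next
    if (codes$role[j] == "therapy") {
      rows[[length(rows) + 1L]] <- data.frame(date = ev$date[i], system = ev$system[i],
                                              code = ev$code[i],
                                              group = codes$treatment_group[j],
                                              type = codes$cancer_type[j])
    } else if (codes$role[j] == "study_marker") {
      q <- quarter_of(ev$date[i])
      if (codes$treatment_group[j] == "Study") {
        rows[[length(rows) + 1L]] <- data.frame(date = ev$date[i], system = ev$system[i],
                                                code = ev$code[i], group = "Study",
                                                type = "none", stringsAsFactors = FALSE)
        study_primary_q <- c(study_primary_q, q)
        attr(rows[[length(rows)]], "needs_pair") <- TRUE
      } else companion_q <- c(companion_q, q)
    }
  }
  if (!length(rows)) return(NULL)
  keep <- vapply(rows, function(r)
    is.null(attr(r, "needs_pair")) || quarter_of(r$date) %in% companion_q, logical(1))
  rows <- rows[keep]
  if (!length(rows)) return(NULL)
  out <- do.call(rbind, rows)
  out[order(out$date, out$system, out$code, method = "radix"), , drop = FALSE]
}

oracle_group <- function(win) {
  if (any(win$group == "Immunotherapy")) return("Immunotherapy")
  if (any(win$group == "Inhibitors")) return("Inhibitors")
  if (any(win$group == "Chemotherapy")) return("Chemotherapy")
  if (any(win$group == "Radiotherapy")) return("Radiotherapy")
  if (any(win$group == "Study")) return("Study")
  NA_character_
}

oracle_lines <- function(rec, index_q, codes, window = 30L,
                         horizon_end = as.Date("2019-12-31")) {
  te <- oracle_therapy_events(rec, codes)
  if (is.null(te)) return(NULL)
  first <- NULL
  d <- quarter_start(index_q)
  while (d <= quarter_end(quarter_shift(index_q, 1L))) {
    if (any(te$date == d)) {
      win <- te[te$date >= d & te$date <= d + window, , drop = FALSE]
      first <- list(start = d, window_end = d + window,
                    group = oracle_group(win), win = win)
      break
    }
    d <- d + 1L
  }
  if (is.null(first)) return(NULL)
  seen <- unique(paste(first$win$system, first$win$code))
  second <- NULL
  d <- first$start + window + 1L
  while (d <= horizon_end) {
    cand <- te[te$date == d & !paste(te$system, te$code) %in% seen, , drop = FALSE]
    if (nrow(cand)) {
      win <- te[te$date >= d & te$date <= d + window, , drop = FALSE]
      second <- list(start = d, window_end = d + window,
                     group = oracle_group(win), win = win)
      break
    }
    d <- d + 1L
  }
  list(first = first, second = second)
}

shared_codes <- load_code_table()
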