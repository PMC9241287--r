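# Drug panels used by the generator, keyed to the bundled code table.
NSCLC_CHEMO_ATC <- c("L01BA04", "L01BC05", "L01CA04", "L01CD01")
SCLC_CHEMO_ATC  <- c("L01CB01", "L01XA02", "L01XX17", "L01DB01")
NSCLC_IMMUNO_ATC <- c("L01XC18", "L01XC17", "L01XC32")
NSCLC_INHIB_ATC  <- c("L01XE02", "L01XE03", "L01XE13", "L01XE35")
UNTYPED_CHEMO_ATC <- c("L01XA01", "L01CD02")
BACKGROUND_ATC <- "C07AB02"   # beta blocker; deliberately outside the code table

#' Scenario configuration for the synthetic claims generator
#'
#' Defaults emulate the population structure of the published study: index
#' diagnoses in 2015--2016, an 80:20 NSCLC:SCLC mixture, 60% of incident
#' patients with a first-line therapy, exclusion-category contamination at
#' the published attrition proportions (30.9% other primary tumours, 4.0%
#' insufficient pre-observation, 10.5% insufficient post-observation), and a
#' predominantly urban (79%), older population.
#'
#' @param n_patients number of insured persons to simulate.
#' @param seed integer seed; one pseudo-random stream is derived per patient
#'   from `(seed, patient index)` so populations are stable under subsetting.
#' @param lc_fraction probability a patient is an incident lung-cancer case.
#' @param type_mixture named probabilities `c(NSCLC=, SCLC=)` among true LC.
#' @param stage_mixture named probabilities over
#'   `no_mets`, `lymph_node`, `distant`.
#' @param treated_fraction probability an (includable) incident case starts a
#'   first-line therapy in the index or following quarter.
#' @param group_mixture named probabilities over the five treatment groups;
#'   renormalised over the feasible groups for true-SCLC patients (no
#'   SCLC-approved immunotherapy/inhibitor exists in the code table).
#' @param off_label_rate probability a treated, type-specific patient also
#'   receives a drug approved for the other cancer type inside the first-line
#'   window.
#' @param exclusion_rates named probabilities for the planned, mutually
#'   exclusive exclusion categories `other_primary`, `short_pre_observation`,
#'   `short_post_observation`.
#' @param m2q_fraction probability diagnosis confirmation happens via two
#'   outpatient quarters rather than one confirmed inpatient coding.
#' @param second_line_fraction probability a treated patient starts a second
#'   line.
#' @param urban_fraction probability of urban residence.
#' @param age_mixture two-point age mixture (means, common sd, weight of the
#'   younger component).
#' @param contact_rates mean per-quarter counts of background primary-care,
#'   specialist, pharmacy and outpatient-hospital contacts (Poisson).
#' @param index_period first/last day of the index period.
#' @param horizon first/last day of the data horizon (enrollment default).
#' @return list of class `scenario_config`.
#' @export
scenario_config <- function(n_patients = 1000L, seed = 1L,
                            lc_fraction = 0.7,
                            type_mixture = c(NSCLC = 0.8, SCLC = 0.2),
                            stage_mixture = c(no_mets = 0.3, lymph_node = 0.2, distant = 0.5),
                            treated_fraction = 0.6,
                            group_mixture = c(Immunotherapy = 0.10, Inhibitors = 0.05,
                                              Chemotherapy = 0.60, Radiotherapy = 0.20,
                                              Study = 0.05),
                            off_label_rate = 0.1,
                            exclusion_rates = c(other_primary = 0.309,
                                                short_pre_observation = 0.04,
                                                short_post_observation = 0.105),
                            m2q_fraction = 0.5,
                            second_line_fraction = 0.25,
                            urban_fraction = 0.79,
                            age_mixture = list(young_mean = 52, old_mean = 71,
                                               sd = 6, young_weight = 0.25),
                            contact_rates = c(gp = 1.5, specialist = 1.0,
                                              pharmacy = 1.2, outpatient_hospital = 0.3),
                            index_period = as.Date(c("2015-01-01", "2016-12-31")),
                            horizon = as.Date(c("2013-01-01", "2018-12-31"))) {
  cfg <- list(n_patients = as.integer(n_patients), seed = as.integer(seed),
              lc_fraction = lc_fraction, type_mixture = type_mixture,
              stage_mixture = stage_mixture, treated_fraction = treated_fraction,
              group_mixture = group_mixture, off_label_rate = off_label_rate,
              exclusion_rates = exclusion_rates, m2q_fraction = m2q_fraction,
              second_line_fraction = second_line_fraction,
              urban_fraction = urban_fraction, age_mixture = age_mixture,
              contact_rates = contact_rates,
              index_period = as.Date(index_period), horizon = as.Date(horizon))
  probs <- c(cfg$lc_fraction, cfg$treated_fraction, cfg$off_label_rate,
             cfg$m2q_fraction, cfg$second_line_fraction, cfg$urban_fraction,
             cfg$type_mixture, cfg$stage_mixture, cfg$group_mixture, cfg$exclusion_rates)
  if (any(probs < 0 | probs > 1)) stop("config error: probabilities must lie in [0, 1]")
  for (nm in c("type_mixture", "stage_mixture", "group_mixture"))
    if (abs(sum(cfg[[nm]]) - 1) > 1e-8) stop("config error: ", nm, " must sum to 1")
  if (sum(cfg$exclusion_rates) > 1) stop("config error: exclusion rates sum above 1")
  sclc_feasible <- sum(cfg$group_mixture[c("Chemotherapy", "Radiotherapy", "Study")])
  if (cfg$type_mixture["SCLC"] > 0 && cfg$treated_fraction > 0 &&
      cfg$lc_fraction > 0 && sclc_feasible <= 0)
    stop("config error: group_mixture puts no mass on any SCLC-feasible treatment group")
  class(cfg) <- "scenario_config"
  cfg
}

# pick an index into cumulative weights from a single uniform
pick <- function(u, weights) {
  cw <- cumsum(weights) / sum(weights)
  findInterval(u, cw, left.open = TRUE) + 1L
}

#' Generate a synthetic SHI claims population with ground truth
#'
#' Emits a [claims_data()] object plus one truth row per patient recording
#' what the generator planted (incidence, cancer type, stage, index quarter,
#' line groups, planned exclusion), so the whole phenotyping pipeline can be
#' validated by parameter recovery. Fully deterministic under
#' `cfg$seed`; each patient has an own derived stream, and the uniform that
#' decides off-label contamination is drawn unconditionally, so populations
#' generated at different `off_label_rate` are nested.
#'
#' @param cfg a [scenario_config()].
#' @return list with elements `claims` ([claims_data()]) and `truth`
#'   (data.frame).
#' @export
generate_population <- function(cfg) {
  stopifnot(inherits(cfg, "scenario_config"))
  n_pat <- cfg$n_patients
  # per-patient accumulators flushed into a preallocated list; one final
  # column bind is orders of magnitude faster than growing global tables
  events_by_pat <- vector("list", n_pat)
  stays_by_pat <- vector("list", n_pat)
  p_pid <- character(n_pat); p_by <- integer(n_pat); p_gen <- character(n_pat)
  p_mun <- character(n_pat); en_start <- numeric(n_pat); en_end <- numeric(n_pat)
  t_lc <- logical(n_pat); t_type <- character(n_pat); t_stage <- character(n_pat)
  t_iq <- character(n_pat); t_fl <- character(n_pat); t_sl <- character(n_pat)
  t_excl <- character(n_pat)

  ev_rows <- vector("list", 64L); ev_n <- 0L
  st_rows <- vector("list", 8L); st_n <- 0L
  emit_ev <- function(pid, date, kind, system, code, setting, provider, confirmed = FALSE) {
    n <- max(length(date), length(code))
    ev_n <<- ev_n + 1L
    ev_rows[[ev_n]] <<- list(pid = rep_len(pid, n),
                             date = rep_len(as.numeric(as.Date(date)), n),
                             kind = rep_len(kind, n), sys = rep_len(system, n),
                             code = rep_len(code, n), set = rep_len(setting, n),
                             prov = rep_len(provider, n), conf = rep_len(confirmed, n))
  }
  emit_stay <- function(pid, adm, dis) {
    st_n <<- st_n + 1L
    st_rows[[st_n]] <<- list(pid = pid, adm = as.numeric(adm), dis = as.numeric(dis))
  }
  flush_patient <- function(i) {
    if (ev_n > 0L) events_by_pat[[i]] <<- ev_rows[seq_len(ev_n)]
    if (st_n > 0L) stays_by_pat[[i]] <<- st_rows[seq_len(st_n)]
    ev_n <<- 0L; st_n <<- 0L
  }

  period_q <- quarter_of(cfg$index_period[1L]):quarter_of(cfg$index_period[2L])
  horizon_end <- cfg$horizon[2L]

  # one decorrelated stream per patient, drawn from a single seeded master
  # stream; the prefix is stable, so smaller populations under the same seed
  # are strict subsets of larger ones
  set.seed(cfg$seed)
  pat_seeds <- sample.int(2147483646L, n_pat, replace = TRUE)

  for (i in seq_len(cfg$n_patients)) {
    set.seed(pat_seeds[i])
    pid <- sprintf("P%06d", i)
    u <- stats::runif(24L)   # fixed decision block; indices documented below

    is_lc <- u[1L] < cfg$lc_fraction
    gender <- if (u[2L] < 0.63) "male" else "female"
    region <- if (u[3L] < cfg$urban_fraction) "urban" else "rural"
    am <- cfg$age_mixture
    mean_age <- if (u[4L] < am$young_weight) am$young_mean else am$old_mean
    age <- max(18L, min(95L, as.integer(round(stats::qnorm(u[5L], mean_age, am$sd)))))

    enr_start <- cfg$horizon[1L]; enr_end <- cfg$horizon[2L]

    if (!is_lc) {
      birth_year <- 2015L - age
      if (u[6L] < 0.10)   # some background patients carry other tumours
        emit_ev(pid, as.Date("2015-06-15"), "diagnosis", "ICD10GM",
                c("C50", "C18", "C64")[pick(u[7L], c(1, 1, 1))], "outpatient", "oncologist")
      k <- stats::rpois(1L, 2)
      if (k > 0) {
        days <- as.Date("2015-01-01") + sample.int(700L, min(k, 700L))
        emit_ev(pid, days, "contact", "", "", "outpatient", "primary_care")
      }
      p_pid[i] <- pid; p_by[i] <- birth_year; p_gen[i] <- gender; p_mun[i] <- region
      en_start[i] <- as.numeric(enr_start); en_end[i] <- as.numeric(enr_end)
      t_lc[i] <- FALSE; t_type[i] <- "none"; t_stage[i] <- NA_character_
      t_iq[i] <- NA_character_; t_fl[i] <- "none"; t_sl[i] <- "none"
      t_excl[i] <- "none"
      flush_patient(i)
      next
    }

    # --- incident lung-cancer case ---------------------------------------
    index_q <- period_q[pick(u[8L], rep(1, length(period_q)))]
    iq_start <- quarter_start(index_q); iq_end <- quarter_end(index_q)
    index_date <- iq_start + floor(u[9L] * as.integer(iq_end - iq_start + 1L))
    birth_year <- quarter_year(index_q) - age

    true_type <- c("NSCLC", "SCLC")[pick(u[10L], cfg$type_mixture)]
    stage <- c("no_mets", "lymph_node_mets", "distant_mets")[pick(u[11L], cfg$stage_mixture)]
    m2q_path <- u[12L] < cfg$m2q_fraction
    excl_i <- pick(u[13L], c(cfg$exclusion_rates, 1 - sum(cfg$exclusion_rates)))
    planned <- c("other_primary_tumor", "insufficient_pre_observation",
                 "insufficient_post_observation", "none")[excl_i]

    if (planned == "insufficient_pre_observation")
      enr_start <- quarter_start(quarter_shift(index_q, -5L))
    if (planned == "insufficient_post_observation") {
      enr_end <- iq_end
      m2q_path <- FALSE   # confirmation must not depend on post-index quarters
    }

    # index diagnosis + confirmation
    if (m2q_path) {
      emit_ev(pid, index_date, "diagnosis", "ICD10GM", "C34", "outpatient", "pulmonologist")
      confq <- quarter_shift(index_q, 1L + (pick(u[14L], c(1, 1, 1)) - 1L))
      emit_ev(pid, quarter_start(confq) + 9L, "diagnosis", "ICD10GM", "C34",
              "outpatient", "pulmonologist")
    } else {
      emit_ev(pid, index_date, "diagnosis", "ICD10GM", "C34", "inpatient", "hospital",
              confirmed = TRUE)
      stay_len <- 5L + as.integer(floor(u[15L] * 10))
      emit_stay(pid, index_date, min(index_date + stay_len, enr_end))
      fuq <- quarter_shift(index_q, 1L + (pick(u[14L], c(1, 1, 1)) - 1L))
      fud <- quarter_start(fuq) + 9L
      if (fud <= enr_end)
        emit_ev(pid, fud, "diagnosis", "ICD10GM", "C34", "outpatient", "pulmonologist")
    }
    if (stage == "lymph_node_mets")
      emit_ev(pid, index_date, "diagnosis", "ICD10GM", "C77",
              if (m2q_path) "outpatient" else "inpatient",
              if (m2q_path) "pulmonologist" else "hospital")
    if (stage == "distant_mets")
      emit_ev(pid, index_date, "diagnosis", "ICD10GM", if (u[16L] < 0.5) "C78" else "C79",
              if (m2q_path) "outpatient" else "inpatient",
              if (m2q_path) "pulmonologist" else "hospital")
    if (planned == "other_primary_tumor") {
      oq <- quarter_shift(index_q, as.integer(floor(u[17L] * 17)) - 8L)
      emit_ev(pid, quarter_start(oq) + 4L, "diagnosis", "ICD10GM",
              c("C50", "C18", "C64")[pick(u[18L], c(1, 1, 1))], "outpatient", "oncologist")
    }

    # therapy
    treated <- u[19L] < cfg$treated_fraction &&
      planned != "insufficient_post_observation"
    fl_group <- "none"; sl_group <- "none"
    feasible <- if (true_type == "SCLC")
      cfg$group_mixture * c(Immunotherapy = 0, Inhibitors = 0, Chemotherapy = 1,
                            Radiotherapy = 1, Study = 1)[names(cfg$group_mixture)]
    else cfg$group_mixture
    two_q_days <- as.integer(quarter_end(quarter_shift(index_q, 1L)) - iq_start + 1L)
    fl_start <- iq_start + floor(u[20L] * two_q_days)
    off_u <- u[21L]          # off-label decision: unconditional, fixed position
    drug_u <- u[22L]; second_u <- u[23L]; extra_u <- u[24L]

    if (treated && sum(feasible) > 0) {
      fl_group <- names(cfg$group_mixture)[pick(drug_u, feasible)]
      typed <- switch(fl_group,
        Chemotherapy = if (true_type == "NSCLC") NSCLC_CHEMO_ATC else SCLC_CHEMO_ATC,
        Immunotherapy = NSCLC_IMMUNO_ATC,
        Inhibitors = NSCLC_INHIB_ATC,
        NULL)
      if (fl_group %in% c("Chemotherapy", "Immunotherapy", "Inhibitors")) {
        drug <- typed[pick(extra_u, rep(1, length(typed)))]
        emit_ev(pid, fl_start + c(0L, 21L), "dispensing", "ATC", drug, "none", "pharmacy")
        if (fl_group == "Chemotherapy" && u[16L] < 0.5)
          emit_ev(pid, fl_start, "dispensing", "ATC", UNTYPED_CHEMO_ATC[1L], "none", "pharmacy")
        if (off_u < cfg$off_label_rate) {
          opp <- if (true_type == "NSCLC") SCLC_CHEMO_ATC else NSCLC_CHEMO_ATC
          emit_ev(pid, fl_start + 7L, "dispensing", "ATC",
                  opp[pick(u[18L], rep(1, length(opp)))], "none", "pharmacy")
        }
      } else if (fl_group == "Radiotherapy") {
        emit_ev(pid, fl_start + c(0L, 7L, 14L, 21L), "procedure", "EBM", "25321",
                "outpatient", "radiologist")
      } else { # Study
        emit_ev(pid, fl_start, "procedure", "EBM", "13461", "outpatient", "pulmonologist")
        emit_ev(pid, fl_start, "procedure", "EBM", "02100", "outpatient", "pulmonologist")
      }

      if (second_u < cfg$second_line_fraction) {
        sl_start <- fl_start + 31L + as.integer(floor(u[14L] * 30))
        used <- character(0)
        if (fl_group %in% c("Chemotherapy", "Immunotherapy", "Inhibitors")) {
          used <- drug
          if (fl_group == "Chemotherapy" && u[16L] < 0.5) used <- c(used, UNTYPED_CHEMO_ATC[1L])
          if (off_u < cfg$off_label_rate) used <- c(used, if (true_type == "NSCLC")
            SCLC_CHEMO_ATC else NSCLC_CHEMO_ATC)  # conservative: avoid reusing any
        }
        cand_inhib <- if (true_type == "NSCLC") setdiff(NSCLC_INHIB_ATC, used) else character(0)
        cand_chemo <- setdiff(if (true_type == "NSCLC") NSCLC_CHEMO_ATC else SCLC_CHEMO_ATC, used)
        if (true_type == "NSCLC" && u[17L] < 0.5 && length(cand_inhib)) {
          sl_group <- "Inhibitors"
          drug2 <- cand_inhib[pick(u[15L], rep(1, length(cand_inhib)))]
        } else if (length(cand_chemo)) {
          sl_group <- "Chemotherapy"
          drug2 <- cand_chemo[pick(u[15L], rep(1, length(cand_chemo)))]
        } else drug2 <- NULL
        if (!is.null(drug2) && sl_start + 21L <= enr_end)
          emit_ev(pid, sl_start + c(0L, 21L), "dispensing", "ATC", drug2, "none", "pharmacy")
        else sl_group <- "none"
      }
    } else fl_start <- as.Date(NA)

    # diagnostics / surgery
    if (u[6L] < 0.25 && stage != "distant_mets" &&
        planned != "insufficient_post_observation")
      emit_ev(pid, index_date + 10L, "procedure", "OPS", "5-3240", "inpatient", "hospital")
    if (u[7L] < 0.80)
      emit_ev(pid, min(index_date + 2L, enr_end), "procedure", "OPS", "1-6200",
              if (m2q_path) "outpatient" else "inpatient",
              if (m2q_path) "pulmonologist" else "hospital")
    if (u[5L] < 0.15)
      emit_ev(pid, min(index_date + 5L, enr_end), "procedure", "EBM", "19321",
              "outpatient", "pulmonologist")

    # background utilisation around the index quarter
    cr <- cfg$contact_rates
    for (r in -5:9) {
      qo <- quarter_shift(index_q, r)
      qs <- quarter_start(qo); qe <- quarter_end(qo)
      if (qe < enr_start || qs > enr_end) next
      qs <- max(qs, enr_start); qe <- min(qe, enr_end)
      len <- as.integer(qe - qs + 1L)
      draw_days <- function(lambda) {
        k <- min(stats::rpois(1L, lambda), len)
        if (k > 0) qs + sample.int(len, k) - 1L else as.Date(character(0))
      }
      d <- draw_days(cr[["gp"]])
      if (length(d)) emit_ev(pid, d, "contact", "", "", "outpatient", "primary_care")
      d <- draw_days(cr[["specialist"]])
      if (length(d)) emit_ev(pid, d, "contact", "", "", "outpatient",
                             SPECIALIST_PROVIDERS[(i %% 5L) + 1L])
      d <- draw_days(cr[["pharmacy"]])
      if (length(d)) emit_ev(pid, d, "dispensing", "ATC", BACKGROUND_ATC, "none", "pharmacy")
      d <- draw_days(cr[["outpatient_hospital"]])
      if (length(d)) emit_ev(pid, d, "contact", "", "", "outpatient", "hospital")
    }

    p_pid[i] <- pid; p_by[i] <- birth_year; p_gen[i] <- gender; p_mun[i] <- region
    en_start[i] <- as.numeric(enr_start); en_end[i] <- as.numeric(enr_end)
    t_lc[i] <- TRUE; t_type[i] <- true_type; t_stage[i] <- stage
    t_iq[i] <- quarter_label(index_q); t_fl[i] <- fl_group; t_sl[i] <- sl_group
    t_excl[i] <- planned
    flush_patient(i)
  }

  patients <- data.frame(patient_id = p_pid, birth_year = p_by,
                         gender = p_gen, municipality = p_mun)
  enrollment <- data.frame(patient_id = p_pid,
                           start = as.Date(en_start, origin = "1970-01-01"),
                           end = as.Date(en_end, origin = "1970-01-01"))
  all_ev <- unlist(events_by_pat, recursive = FALSE, use.names = FALSE)
  col <- function(rows, nm) unlist(lapply(rows, `[[`, nm), use.names = FALSE)
  events <- if (length(all_ev))
    data.frame(patient_id = col(all_ev, "pid"),
               date = as.Date(col(all_ev, "date"), origin = "1970-01-01"),
               kind = col(all_ev, "kind"), system = col(all_ev, "sys"),
               code = col(all_ev, "code"), setting = col(all_ev, "set"),
               provider = col(all_ev, "prov"), confirmed = col(all_ev, "conf"))
  else data.frame(patient_id = character(0), date = as.Date(character(0)),
                  kind = character(0), system = character(0), code = character(0),
                  setting = character(0), provider = character(0),
                  confirmed = logical(0))
  all_st <- unlist(stays_by_pat, recursive = FALSE, use.names = FALSE)
  stays <- if (length(all_st))
    data.frame(patient_id = col(all_st, "pid"),
               admission = as.Date(col(all_st, "adm"), origin = "1970-01-01"),
               discharge = as.Date(col(all_st, "dis"), origin = "1970-01-01"),
               mode = "inpatient")
  else data.frame(patient_id = character(0), admission = as.Date(character(0)),
                  discharge = as.Date(character(0)), mode = character(0))
  truth <- data.frame(patient_id = p_pid, is_incident_lc = t_lc, true_type = t_type,
                      true_stage = t_stage, true_index_quarter = t_iq,
                      true_first_line_group = t_fl, true_second_line_group = t_sl,
                      planned_exclusion_reason = t_excl)
  list(claims = claims_data(patients, enrollment, events, stays), truth = truth)
}

#' Append the fixed edge-case panel
#'
#' Adds a hand-built panel of boundary patients to a generated population (or
#' to an empty one): diagnosis on a quarter's last day; a new drug exactly 30
#' vs 31 days after first-line start; simultaneous NSCLC- and SCLC-specific
#' dispensings; C77 and C78 both coded; a single unconfirmed outpatient
#' diagnosis; a prior lung-cancer coding at exactly index-8 vs index-9
#' quarters; a confirming outpatient diagnosis just inside vs just outside
#' the observation horizon; a biomarker test with hospital discharge exactly
#' 14 vs 15 days before; a hospital stay spanning a year boundary.
#'
#' @param pop list with `claims` and `truth` as returned by
#'   [generate_population()], or `NULL` for a panel-only population.
#' @return list with `claims` and `truth`, panel appended.
#' @export
inject_edge_cases <- function(pop = NULL) {
  D <- as.Date
  pt <- list(); en <- list(); ev <- list(); st <- list(); tr <- list()
  addp <- function(pid, enr_start = "2013-01-01", enr_end = "2018-12-31") {
    pt[[pid]] <<- data.frame(patient_id = pid, birth_year = 1950L,
                             gender = "male", municipality = "urban")
    en[[pid]] <<- data.frame(patient_id = pid, start = D(enr_start), end = D(enr_end))
  }
  adde <- function(pid, date, kind, system, code, setting, provider, confirmed = FALSE)
    ev[[length(ev) + 1L]] <<- data.frame(patient_id = pid, date = D(date), kind = kind,
                                         system = system, code = code, setting = setting,
                                         provider = provider, confirmed = confirmed)
  adds <- function(pid, adm, dis)
    st[[length(st) + 1L]] <<- data.frame(patient_id = pid, admission = D(adm),
                                         discharge = D(dis), mode = "inpatient")
  addt <- function(pid, planned = "none", type = "none", stage = NA_character_,
                   iq = NA_character_, fl = "none", sl = "none")
    tr[[pid]] <<- data.frame(patient_id = pid, is_incident_lc = TRUE, true_type = type,
                             true_stage = stage, true_index_quarter = iq,
                             true_first_line_group = fl, true_second_line_group = sl,
                             planned_exclusion_reason = planned)
  dx <- function(pid, date, code = "C34", setting = "outpatient",
                 provider = "pulmonologist", confirmed = FALSE)
    adde(pid, date, "diagnosis", "ICD10GM", code, setting, provider, confirmed)
  inpat_dx <- function(pid, date) dx(pid, date, setting = "inpatient",
                                     provider = "hospital", confirmed = TRUE)
  disp <- function(pid, date, atc) adde(pid, date, "dispensing", "ATC", atc, "none", "pharmacy")

  addp("EC-BOUNDARY-DAY")
  dx("EC-BOUNDARY-DAY", "2015-03-31")          # last day of 2015Q1
  dx("EC-BOUNDARY-DAY", "2015-07-02")
  addt("EC-BOUNDARY-DAY", type = "none", stage = "no_mets", iq = "2015Q1")

  addp("EC-30DAY"); addp("EC-31DAY")           # second-line trigger boundary
  for (p in c("EC-30DAY", "EC-31DAY")) {
    inpat_dx(p, "2015-02-01"); adds(p, "2015-02-01", "2015-02-05")
    dx(p, "2015-05-10")
    disp(p, "2015-02-10", "L01XA02")           # first line starts 2015-02-10
  }
  disp("EC-30DAY", "2015-03-12", "L01BC05")    # start + 30: inside the window
  disp("EC-31DAY", "2015-03-13", "L01BC05")    # start + 31: opens second line
  addt("EC-30DAY", type = "SCLC", stage = "no_mets", iq = "2015Q1", fl = "Chemotherapy")
  addt("EC-31DAY", type = "SCLC", stage = "no_mets", iq = "2015Q1",
       fl = "Chemotherapy", sl = "Chemotherapy")

  addp("EC-CONFLICT-DRUGS")                    # NSCLC + SCLC drug in one window
  inpat_dx("EC-CONFLICT-DRUGS", "2015-02-01"); dx("EC-CONFLICT-DRUGS", "2015-05-10")
  disp("EC-CONFLICT-DRUGS", "2015-02-10", "L01XC18")
  disp("EC-CONFLICT-DRUGS", "2015-02-20", "L01XA02")
  addt("EC-CONFLICT-DRUGS", type = "none", stage = "no_mets", iq = "2015Q1",
       fl = "Immunotherapy")

  addp("EC-C77-C78")                           # stage precedence
  inpat_dx("EC-C77-C78", "2015-02-01"); dx("EC-C77-C78", "2015-05-10")
  dx("EC-C77-C78", "2015-02-01", code = "C77")
  dx("EC-C77-C78", "2015-02-01", code = "C78")
  addt("EC-C77-C78", type = "none", stage = "distant_mets", iq = "2015Q1")

  addp("EC-SINGLE-UNCONFIRMED")                # fails both confirmation branches
  dx("EC-SINGLE-UNCONFIRMED", "2015-02-01")
  addt("EC-SINGLE-UNCONFIRMED", planned = "not_confirmed", iq = "2015Q1")

  addp("EC-YEAR-STAY")                         # stay spanning a year boundary
  inpat_dx("EC-YEAR-STAY", "2015-11-15"); dx("EC-YEAR-STAY", "2016-02-10")
  adds("EC-YEAR-STAY", "2015-12-28", "2016-01-03")
  addt("EC-YEAR-STAY", type = "none", stage = "no_mets", iq = "2015Q4")

  addp("EC-WASHOUT-IN", enr_start = "2012-01-01")   # prior coding at index-8
  inpat_dx("EC-WASHOUT-IN", "2015-02-01"); dx("EC-WASHOUT-IN", "2015-05-10")
  dx("EC-WASHOUT-IN", "2013-02-01")                 # 2013Q1 = index-8: washout fails
  addt("EC-WASHOUT-IN", planned = "prior_lc_diagnosis", iq = "2015Q1")
  addp("EC-WASHOUT-OUT", enr_start = "2012-01-01")  # prior coding at index-9
  inpat_dx("EC-WASHOUT-OUT", "2015-02-01"); dx("EC-WASHOUT-OUT", "2015-05-10")
  dx("EC-WASHOUT-OUT", "2012-11-01")                # 2012Q4 = index-9: passes
  addt("EC-WASHOUT-OUT", iq = "2015Q1", stage = "no_mets")

  addp("EC-M2Q-IN")                            # confirming coding inside horizon
  dx("EC-M2Q-IN", "2015-02-01"); dx("EC-M2Q-IN", "2018-11-01")
  addt("EC-M2Q-IN", iq = "2015Q1", stage = "no_mets")
  addp("EC-M2Q-OUT", enr_end = "2019-12-31")   # confirming coding outside horizon
  dx("EC-M2Q-OUT", "2015-02-01"); dx("EC-M2Q-OUT", "2019-02-01")
  addt("EC-M2Q-OUT", planned = "not_confirmed", iq = "2015Q1")

  addp("EC-BIO-14"); addp("EC-BIO-15")         # inpatient-attribution lookback
  for (p in c("EC-BIO-14", "EC-BIO-15")) {
    inpat_dx(p, "2015-02-01"); dx(p, "2015-05-10")
    adde(p, "2015-03-01", "procedure", "EBM", "19321", "outpatient", "pulmonologist")
  }
  adds("EC-BIO-14", "2015-02-10", "2015-02-15")  # discharge = test - 14: inpatient
  adds("EC-BIO-15", "2015-02-10", "2015-02-14")  # discharge = test - 15: outpatient
  addt("EC-BIO-14", iq = "2015Q1", stage = "no_mets")
  addt("EC-BIO-15", iq = "2015Q1", stage = "no_mets")

  panel <- list(patients = do.call(rbind, unname(pt)),
                enrollment = do.call(rbind, unname(en)),
                events = do.call(rbind, ev),
                stays = do.call(rbind, st),
                truth = do.call(rbind, unname(tr)))
  if (is.null(pop)) {
    claims <- claims_data(panel$patients, panel$enrollment, panel$events, panel$stays)
    return(list(claims = claims, truth = panel$truth))
  }
  claims <- claims_data(rbind(pop$claims$patients, panel$patients),
                        rbind(pop$claims$enrollment, panel$enrollment),
                        rbind(pop$claims$events[EVENT_COLS], panel$events),
                        rbind(pop$claims$stays, panel$stays))
  truth <- rbind(pop$truth, panel$truth)
  rownames(truth) <- NULL
  list(claims = claims, truth = truth)
}
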