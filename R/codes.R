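#' @keywords internal
CODE_SYSTEMS <- c("ICD10GM", "ATC", "OPS", "EBM")
#' @keywords internal
TREATMENT_GROUPS <- c("Immunotherapy", "Inhibitors", "Chemotherapy", "Radiotherapy", "Study")
#' @keywords internal
CANCER_TYPES <- c("NSCLC", "SCLC")
#' @keywords internal
CODE_ROLES <- c("lc_diagnosis", "other_primary", "lymph_met", "distant_met", "therapy",
                "biomarker", "bronchoscopy", "surgery", "study_marker",
                "inpatient_chemo_marker", "other")

# Normalisation used for every code that enters the system. Claims sources and
# the printed literature disagree on punctuation: OPS codes appear as "8-542",
# "8–542" (en-dash) or "8 542"; ICD and OPS sub-codes carry dots
# ("C34.1", "1-690.0"); wildcard families are marked with a trailing
# "×" or "x". Canonical form: uppercase, dots/spaces removed, any dash
# variant collapsed to a single ASCII hyphen, wildcard suffix stripped (and
# remembered as a prefix marker).
norm_code_info <- function(raw) {
  raw <- as.character(raw)
  if (any(is.na(raw) | !nzchar(trimws(raw))))
    stop("invalid code: empty code string")
  x <- toupper(trimws(raw))
  x <- gsub("[–—−]", "-", x)         # en/em dash, minus sign
  x <- gsub("[.· ]", "", x)                    # dots, middle dots, spaces
  x <- gsub("-+", "-", x)                           # collapse repeated hyphens
  wildcard <- grepl("×$", x) | grepl("[0-9][X]$", x) & grepl("^[0-9]", x)
  # trailing multiplication sign is always a wildcard; a trailing "X" only on
  # numeric (OPS/EBM-style) codes, so ATC codes like L01XX17 are untouched
  x <- sub("×$", "", x)
  x[wildcard] <- sub("X$", "", x[wildcard])
  x <- sub("-$", "", x)
  if (any(!nzchar(x))) stop("invalid code: nothing left after normalization")
  list(code = x, wildcard = wildcard)
}

#' Normalize a billing code to canonical form
#'
#' Uppercases, strips dots and spaces, converts en-dashes to hyphens and
#' removes trailing wildcard markers ("×"/"x"). Idempotent.
#'
#' @param system one of `"ICD10GM"`, `"ATC"`, `"OPS"`, `"EBM"` (recycled).
#' @param raw raw code string(s) as printed or billed.
#' @return character vector of canonical codes.
#' @examples
#' normalize_code("OPS", "8–542")   # "8-542"
#' normalize_code("ICD10GM", "C34.1")    # "C341"
#' @export
normalize_code <- function(system, raw) {
  if (!all(system %in% CODE_SYSTEMS))
    stop("unknown code system: ", paste(setdiff(system, CODE_SYSTEMS), collapse = ", "))
  norm_code_info(raw)$code
}

#' Load a phenotyping code table
#'
#' Reads the delimited code registry mapping ICD-10-GM / ATC / OPS / EBM codes
#' to phenotyping roles (lung-cancer diagnosis, metastasis markers, therapy
#' with treatment group and cancer type, biomarker/bronchoscopy/surgery
#' detection, study markers). The bundled default transcribes the published
#' drug/procedure assignment table plus the diagnostic code sets; the surgery
#' entries are a clearly labelled synthetic placeholder family and should be
#' replaced with a validated list for real analyses.
#'
#' @param path CSV path; default is the bundled table.
#' @return a `data.frame` of class `code_table` with columns
#'   `system, code, is_prefix, label, treatment_group, cancer_type, role` and
#'   a `"version"` attribute.
#' @export
load_code_table <- function(path = system.file("extdata", "lc_code_table_v1.csv",
                                               package = "lungclaims")) {
  tab <- utils::read.csv(path, colClasses = "character", fileEncoding = "UTF-8")
  need <- c("system", "code", "is_prefix", "label", "treatment_group", "cancer_type", "role")
  if (!all(need %in% names(tab)))
    stop("code table is missing columns: ", paste(setdiff(need, names(tab)), collapse = ", "))
  if (!all(tab$system %in% CODE_SYSTEMS))
    stop("unknown code system: ", paste(setdiff(tab$system, CODE_SYSTEMS), collapse = ", "))
  info <- norm_code_info(tab$code)
  tab$code <- info$code
  tab$is_prefix <- (toupper(tab$is_prefix) %in% c("TRUE", "T", "1")) | info$wildcard |
    (tab$system == "ICD10GM" & nchar(tab$code) == 3L)
  bad_grp <- !tab$treatment_group %in% c(TREATMENT_GROUPS, "none")
  if (any(bad_grp)) stop("unknown treatment_group: ", paste(unique(tab$treatment_group[bad_grp]), collapse = ", "))
  bad_ct <- !tab$cancer_type %in% c(CANCER_TYPES, "none")
  if (any(bad_ct)) stop("unknown cancer_type: ", paste(unique(tab$cancer_type[bad_ct]), collapse = ", "))
  bad_role <- !tab$role %in% CODE_ROLES
  if (any(bad_role)) stop("unknown role: ", paste(unique(tab$role[bad_role]), collapse = ", "))
  if (any(tab$cancer_type != "none" & tab$role != "therapy"))
    stop("cancer_type may only be set on therapy entries")
  key <- paste(tab$system, tab$code)
  if (anyDuplicated(key))
    stop("duplicate (system, code) entries: ", paste(unique(key[duplicated(key)]), collapse = ", "))
  attr(tab, "version") <- sub("[.][^.]*$", "", basename(path))
  class(tab) <- c("code_table", "data.frame")
  tab
}

#' @export
print.code_table <- function(x, ...) {
  cat("Phenotyping code table", attr(x, "version"), "-", nrow(x), "entries\n")
  print(table(system = x$system, role = x$role))
  invisible(x)
}

#' Does a code-table entry match an observed code?
#'
#' Matching is exact on `(system, code)`, extended to prefix semantics for
#' family entries (`is_prefix`) and for 3-character ICD-10 codes, which by
#' convention capture all their 4/5-character children (e.g. `C34` matches
#' `C341`).
#'
#' @param entry a single row of a [load_code_table()] table (data.frame or list).
#' @param system code system of the observed code.
#' @param observed canonical observed code(s) (see [normalize_code()]).
#' @return logical vector along `observed`.
#' @export
code_matches <- function(entry, system, observed) {
  if (is.data.frame(entry)) entry <- as.list(entry[1L, ])
  prefix <- isTRUE(entry$is_prefix) ||
    (entry$system == "ICD10GM" && nchar(entry$code) == 3L)
  system == entry$system &
    (observed == entry$code | (prefix & startsWith(observed, entry$code)))
}

# Vectorised lookup: index of the matching entry for each (system, observed)
# pair, NA when nothing matches. Exact matches win; among prefix entries the
# longest matching prefix wins.
match_codes <- function(codes, system, observed) {
  key <- paste(codes$system, codes$code)
  idx <- match(paste(system, observed), key)
  todo <- which(is.na(idx) & !is.na(observed) & nzchar(observed))
  if (length(todo)) {
    pref <- which(codes$is_prefix)
    pref <- pref[order(nchar(codes$code[pref]), decreasing = TRUE)]
    for (j in pref) {
      hit <- todo[system[todo] == codes$system[j] &
                    startsWith(observed[todo], codes$code[j])]
      idx[hit] <- j
      todo <- setdiff(todo, hit)
      if (!length(todo)) break
    }
  }
  idx
}

#' Treatment-group and cancer-type assignment of a therapy code
#'
#' Looks a canonical ATC/OPS/EBM code up in the code table and returns the
#' published treatment-group and cancer-type assignment. Non-therapy codes
#' (and unknown codes) return `("none", "none")`. Study primary markers
#' return group `"Study"` (pairing with a companion code is enforced at the
#' episode level, not here).
#'
#' @param code canonical code string.
#' @param system code system.
#' @param codes a [load_code_table()] table.
#' @return list with elements `treatment_group` and `cancer_type`.
#' @examples
#' codes <- load_code_table()
#' lookup_therapy("L01XC18", "ATC", codes)  # Immunotherapy / NSCLC
#' lookup_therapy("8-542", "OPS", codes)    # Chemotherapy / none
#' @export
lookup_therapy <- function(code, system, codes) {
  i <- match_codes(codes, system, code)
  if (is.na(i) || !(codes$role[i] %in% c("therapy", "study_marker")) ||
      codes$treatment_group[i] == "none")
    return(list(treatment_group = "none", cancer_type = "none"))
  list(treatment_group = codes$treatment_group[i], cancer_type = codes$cancer_type[i])
}
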