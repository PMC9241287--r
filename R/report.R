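#' Run the full lung-cancer phenotyping pipeline
#'
#' Orchestrates cohort selection, treatment-line construction, cancer-type
#' classification, care attribution and the burden analysis, and assembles
#' the descriptive output tables (attrition flow, demographic and treatment
#' cross-tabulations by cancer type, therapist and diagnostics tables, mean
#' burden series per stratum).
#'
#' @param claims a [claims_data()] object.
#' @param codes a [load_code_table()] table.
#' @param period index period (first/last day).
#' @param obs_end end of the observation horizon.
#' @param window line collection window in days (the published "one month").
#' @param lookback inpatient-attribution lookback in days.
#' @return object of class `lc_phenotype` with components `selection`,
#'   `lines`, `types`, `labels`, `care`, `burden`, `burden_means`,
#'   `attrition`, `tables`, `manifest`.
#' @examples
#' pop <- generate_population(scenario_config(n_patients = 50, seed = 1))
#' fit <- lc_phenotype(pop$claims)
#' fit
#' @export
lc_phenotype <- function(claims, codes = load_code_table(),
                         period = as.Date(c("2015-01-01", "2016-12-31")),
                         obs_end = as.Date("2018-12-31"),
                         window = 30L, lookback = 14L) {
  selection <- select_cohort(claims, period, obs_end)
  ln <- build_lines(claims, selection, codes, window)
  care <- attribute_care(claims, selection, ln, codes, window, lookback)
  burden <- build_burden(claims, selection, ln, obs_end)

  inc <- selection[selection$status == "included", , drop = FALSE]
  typed <- merge(inc, ln$types, by = "patient_id", all.x = TRUE)
  typed <- merge(typed, ln$labels, by = "patient_id", all.x = TRUE)
  typed <- merge(typed, care, by = "patient_id", all.x = TRUE)

  strata <- data.frame(patient_id = typed$patient_id, stratum = typed$call)
  burden_means <- if (nrow(burden))
    suppressWarnings(aggregate_burden(burden, strata))
  else data.frame(stratum = character(0), metric = character(0),
                  relative_quarter = integer(0), mean = numeric(0), n = integer(0))

  tables <- list(
    stage_by_type = crosstab(typed, "stage", "call"),
    age_by_type = crosstab(typed, "age_group", "call"),
    gender_by_type = crosstab(typed, "gender", "call"),
    region_by_type = crosstab(typed, "region", "call"),
    label_by_type = crosstab(typed, "first_line_label", "call"),
    therapist_by_type = crosstab(typed, "therapist_index", "call"),
    bronchoscopy_by_type = crosstab(typed, "bronchoscopy_first", "call"),
    biomarker_by_type = crosstab(typed, "biomarker_first", "call"))

  structure(list(selection = selection, lines = ln$lines, types = ln$types,
                 labels = ln$labels, care = care, burden = burden,
                 burden_means = burden_means,
                 attrition = attrition_table(selection),
                 tables = tables,
                 manifest = list(code_table_version = attr(codes, "version"),
                                 period = format(period), obs_end = format(obs_end),
                                 window = window, lookback = lookback,
                                 n_patients = nrow(claims$patients))),
            class = "lc_phenotype")
}

# one-decimal percentage with half-up rounding (matching the publication's
# printed style); sprintf/round use banker's rounding, hence the floor form
pct1 <- function(x, total) {
  if (total == 0) return(rep(NA_real_, length(x)))
  floor(x / total * 1000 + 0.5) / 10
}

#' Attrition table of a cohort selection
#'
#' Counts and percentages of candidates (patients with an index quarter) that
#' were included or excluded, by exclusion reason. The reasons partition the
#' candidates, so counts sum to the total.
#'
#' @param selection output of [select_cohort()].
#' @return data.frame `group, n, percent`.
#' @export
attrition_table <- function(selection) {
  cand <- selection[selection$status != "no_index", , drop = FALSE]
  total <- nrow(cand)
  groups <- c("included", EXCLUSION_REASONS)
  n <- c(sum(cand$status == "included"),
         vapply(EXCLUSION_REASONS, function(r) sum(cand$exclusion_reason == r), integer(1)))
  out <- data.frame(group = c("candidates", groups),
                    n = c(total, n),
                    percent = c(if (total) 100 else NA_real_, pct1(n, total)))
  rownames(out) <- NULL
  out
}

#' Cross-tabulation with within-column percentages
#'
#' Counts of `row_dim` by `col_dim` with percentages computed within each
#' column over non-missing entries; missing rows are reported separately as
#' `"(missing)"` and excluded from the percentage base.
#'
#' @param data data.frame containing both dimensions.
#' @param row_dim,col_dim column names.
#' @return data.frame in long format: `row, col, n, percent`.
#' @export
crosstab <- function(data, row_dim, col_dim) {
  if (!row_dim %in% names(data) || !col_dim %in% names(data))
    stop("unknown dimension name: ", paste(setdiff(c(row_dim, col_dim), names(data)),
                                           collapse = ", "))
  r <- as.character(data[[row_dim]]); c_ <- as.character(data[[col_dim]])
  c_[is.na(c_)] <- "(missing)"
  miss <- is.na(r)
  r[miss] <- "(missing)"
  rows <- unique(r)[order(unique(r), method = "radix")]
  cols <- unique(c_)[order(unique(c_), method = "radix")]
  out <- do.call(rbind, lapply(cols, function(cc) {
    in_col <- c_ == cc
    base <- sum(in_col & !miss)
    do.call(rbind, lapply(rows, function(rr) {
      n <- sum(in_col & r == rr)
      data.frame(row = rr, col = cc, n = n,
                 percent = if (rr == "(missing)") NA_real_ else pct1(n, base))
    }))
  }))
  rownames(out) <- NULL
  out
}

#' @export
print.lc_phenotype <- function(x, ...) {
  cat("Incident lung-cancer phenotyping\n")
  cat("  patients:", x$manifest$n_patients,
      "| candidates:", x$attrition$n[x$attrition$group == "candidates"],
      "| included:", x$attrition$n[x$attrition$group == "included"], "\n")
  at <- x$attrition
  for (i in which(at$group %in% EXCLUSION_REASONS & at$n > 0))
    cat(sprintf("  excluded (%s): %d (%.1f%%)\n", at$group[i], at$n[i], at$percent[i]))
  tt <- table(x$types$call)
  cat("  cancer-type calls:", paste(sprintf("%s=%d", names(tt), tt), collapse = ", "), "\n")
  invisible(x)
}

#' @export
summary.lc_phenotype <- function(object, ...) {
  structure(object, class = c("summary.lc_phenotype", class(object)))
}

#' @export
print.summary.lc_phenotype <- function(x, ...) {
  print.lc_phenotype(x)
  cat("\nAttrition:\n"); print(x$attrition, row.names = FALSE)
  cat("\nFirst-line label by cancer type (column %):\n")
  print(x$tables$label_by_type, row.names = FALSE)
  invisible(x)
}

#' Plot mean burden series
#'
#' Base-graphics line plot of the mean per-quarter time-expenditure metrics
#' for one stratum (cancer-type call).
#'
#' @param x an `lc_phenotype` object.
#' @param stratum which stratum to plot (default: first available).
#' @param ... passed to [graphics::matplot()].
#' @export
plot.lc_phenotype <- function(x, stratum = NULL, ...) {
  bm <- x$burden_means
  if (!nrow(bm)) { warning("no burden-eligible patients to plot"); return(invisible(x)) }
  if (is.null(stratum)) stratum <- sort(unique(bm$stratum))[1L]
  bm <- bm[bm$stratum == stratum, , drop = FALSE]
  wide <- stats::reshape(bm[c("metric", "relative_quarter", "mean")],
                         direction = "wide", idvar = "relative_quarter",
                         timevar = "metric")
  wide <- wide[order(wide$relative_quarter), , drop = FALSE]
  graphics::matplot(wide$relative_quarter, wide[-1L], type = "b", pch = 1:5,
                    lty = 1, xlab = "quarter relative to index",
                    ylab = "mean count per patient",
                    main = paste("Time expenditure,", stratum), ...)
  graphics::abline(v = 0, lty = 2)
  graphics::legend("topright", legend = sub("^mean\\.", "", names(wide)[-1L]),
                   pch = 1:5, col = 1:5, cex = 0.7, bty = "n")
  invisible(x)
}

#' Render a deterministic plain-text report
#'
#' Formats the attrition flow, the cross-tabulations and the mean burden
#' series as a plain-text report. Output is byte-stable for identical inputs
#' (fixed ordering and number formatting, no timestamps), which the
#' regression tests rely on.
#'
#' @param x an `lc_phenotype` object.
#' @return character vector of report lines.
#' @export
format_report <- function(x) {
  num <- function(v) ifelse(is.na(v), "NA", sprintf("%.1f", v))
  out <- c("# Incident lung-cancer phenotyping report",
           paste0("code_table: ", x$manifest$code_table_version),
           paste0("patients: ", x$manifest$n_patients),
           "", "## Attrition")
  at <- x$attrition
  out <- c(out, sprintf("%s,%d,%s", at$group, at$n, num(at$percent)))
  for (nm in names(x$tables)) {
    tb <- x$tables[[nm]]
    out <- c(out, "", paste0("## ", nm), "row,col,n,percent",
             sprintf("%s,%s,%d,%s", tb$row, tb$col, tb$n, num(tb$percent)))
  }
  bm <- x$burden_means
  out <- c(out, "", "## burden_means", "stratum,metric,relative_quarter,mean,n")
  if (nrow(bm))
    out <- c(out, sprintf("%s,%s,%d,%s,%d", bm$stratum, bm$metric,
                          bm$relative_quarter,
                          ifelse(is.na(bm$mean), "NA", sprintf("%.4f", bm$mean)), bm$n))
  out
}

#' @rdname format_report
#' @param path file to write the report to.
#' @export
write_report <- function(x, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(format_report(x), con, sep = "\n", useBytes = TRUE)
  invisible(path)
}
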