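#' Calendar-quarter arithmetic
#'
#' Claims phenotyping in German SHI data works at quarter resolution: the index
#' quarter, the eight-quarter washout, M2Q confirmation and the burden series
#' are all defined on calendar quarters. Quarters are represented as plain
#' integer ordinals (`year * 4 + quarter - 1`), which makes shifting, ordering
#' and differencing ordinary integer arithmetic.
#'
#' @param year calendar year (integer vector).
#' @param q quarter within the year, 1--4.
#' @return `quarter()`, `quarter_of()`, `quarter_shift()` and
#'   `quarter_parse()` return integer quarter ordinals; `quarter_label()` a
#'   character vector like `"2015Q3"`; `quarter_start()`/`quarter_end()` the
#'   first/last calendar day of the quarter as `Date`.
#' @examples
#' q <- quarter_of(as.Date("2015-02-14"))
#' quarter_label(q)                 # "2015Q1"
#' quarter_label(quarter_shift(q, -8))  # "2013Q1"
#' @export
quarter <- function(year, q) {
  stopifnot(all(q >= 1L & q <= 4L, na.rm = TRUE))
  as.integer(year) * 4L + (as.integer(q) - 1L)
}

#' @rdname quarter
#' @param d a `Date` vector (or something coercible to one).
#' @export
quarter_of <- function(d) {
  d <- as.Date(d)
  lt <- as.POSIXlt(d)
  as.integer(lt$year + 1900L) * 4L + lt$mon %/% 3L
}

#' @rdname quarter
#' @param qo integer quarter ordinal as returned by `quarter()`/`quarter_of()`.
#' @param n signed number of quarters to shift by.
#' @export
quarter_shift <- function(qo, n) as.integer(qo + n)

#' @rdname quarter
#' @export
quarter_year <- function(qo) qo %/% 4L

#' @rdname quarter
#' @export
quarter_num <- function(qo) qo %% 4L + 1L

#' @rdname quarter
#' @export
quarter_label <- function(qo) {
  out <- rep(NA_character_, length(qo))
  ok <- !is.na(qo)
  out[ok] <- sprintf("%dQ%d", qo[ok] %/% 4L, qo[ok] %% 4L + 1L)
  out
}

#' @rdname quarter
#' @param x character labels of the form `"2015Q3"`.
#' @export
quarter_parse <- function(x) {
  m <- regexec("^([0-9]{4})Q([1-4])$", x)
  parts <- regmatches(x, m)
  bad <- !is.na(x) & lengths(parts) != 3L
  if (any(bad)) stop("malformed quarter label(s): ", paste(x[bad], collapse = ", "))
  out <- rep(NA_integer_, length(x))
  ok <- !is.na(x)
  out[ok] <- vapply(parts[ok], function(p) quarter(as.integer(p[2L]), as.integer(p[3L])), integer(1))
  out
}

#' @rdname quarter
#' @export
quarter_start <- function(qo) {
  out <- rep(as.Date(NA), length(qo))
  ok <- !is.na(qo)
  out[ok] <- as.Date(sprintf("%d-%02d-01", qo[ok] %/% 4L, (qo[ok] %% 4L) * 3L + 1L))
  out
}

#' @rdname quarter
#' @export
quarter_end <- function(qo) quarter_start(quarter_shift(qo, 1L)) - 1L
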