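#' @import data.table
#' @importFrom stats dnbinom qnorm pgamma qgamma optim rweibull
#'   rnorm runif rlnorm rgeom median fivenum fisher.test wilcox.test plogis
#'   qlogis uniroot setNames quantile sd
#' @importFrom utils head
NULL

# silence R CMD check notes for data.table NSE columns
utils::globalVariables(c(
  ".", ".N", ".SD", "primaryid", "caseid", "drug_name", "role", "pt",
  "start_ord", "fda_ord", "a", "n_drug", "days", "stratum", "ic025",
  "drug_seq", "documented", "n", "share"
))

#' Round half away from zero
#'
#' Presentation-layer rounding used for all reported percentages: exact
#' halves round up in magnitude (2.5 -> 3), unlike [base::round()]'s
#' round-half-even.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Percentage share with half-up rounding
#'
#' @param n numerator count(s).
#' @param total denominator count.
#' @param digits decimal places (default 2, the convention for baseline
#'   tables; label cross-tabs use 1).
#' @return percentage(s) on the 0-100 scale.
#' @export
share_pct <- function(n, total, digits = 2) {
  stopifnot(total > 0)
  round_half_up(100 * n / total, digits)
}

#' Parse possibly partial FAERS dates
#'
#' FAERS date fields may carry day (YYYYMMDD), month (YYYYMM) or year (YYYY)
#' precision, or be blank. For ordering, partial dates are completed to the
#' earliest possible day; the completion is used only to compare, never to
#' compute day differences.
#'
#' @param raw character vector of raw date strings.
#' @return data.frame with columns `date` (Date, earliest-day completion),
#'   `precision` (one of day/month/year/none) and `ord` (numeric YYYYMMDD
#'   ordering key, NA when precision is none).
#' @export
parse_partial_date <- function(raw) {
  raw <- as.character(raw)
  raw[is.na(raw)] <- ""
  raw <- trimws(raw)
  digits <- grepl("^[0-9]+$", raw) & nzchar(raw)
  prec <- rep("none", length(raw))
  prec[digits & nchar(raw) == 4L] <- "year"
  prec[digits & nchar(raw) == 6L] <- "month"
  prec[digits & nchar(raw) == 8L] <- "day"
  comp <- rep(NA_character_, length(raw))
  comp[prec == "year"] <- paste0(raw[prec == "year"], "0101")
  comp[prec == "month"] <- paste0(raw[prec == "month"], "01")
  comp[prec == "day"] <- raw[prec == "day"]
  date <- as.Date(comp, format = "%Y%m%d")
  prec[!is.na(comp) & is.na(date)] <- "none"  # e.g. month 13
  ord <- suppressWarnings(as.numeric(comp))
  ord[prec == "none"] <- NA_real_
  data.frame(date = date, precision = prec, ord = ord,
             stringsAsFactors = FALSE)
}

#' Normalize drug names
#'
#' Upper-cases, collapses internal whitespace, and optionally maps reported
#' names to normalized (e.g. brand to generic) names through a synonym table.
#'
#' @param x character vector of reported drug names.
#' @param synonyms optional data.frame with columns `reported_name`,
#'   `normalized_name`; matching is applied after case/whitespace
#'   normalization of both sides.
#' @return normalized character vector.
#' @export
normalize_drug_name <- function(x, synonyms = NULL) {
  out <- toupper(trimws(as.character(x)))
  out <- gsub("[[:space:]]+", " ", out)
  if (!is.null(synonyms)) {
    stopifnot(all(c("reported_name", "normalized_name") %in% names(synonyms)))
    key <- gsub("[[:space:]]+", " ", toupper(trimws(synonyms$reported_name)))
    val <- gsub("[[:space:]]+", " ", toupper(trimws(synonyms$normalized_name)))
    hit <- match(out, key)
    out[!is.na(hit)] <- val[hit[!is.na(hit)]]
  }
  out
}
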