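#' Packaged reference summary tables
#'
#' Summary tables from a large published FAERS pharmacovigilance analysis of
#' drug-induced alopecia (reports 2004-2024, 181,049 de-duplicated cases),
#' bundled as worked inputs for the package's reporting operations:
#'
#' * `dia_baseline_counts()` — baseline characteristic counts of the
#'   alopecia cases (sex, reporting year, region, reporter occupation,
#'   severity, outcome codes).
#' * `dia_signal_reference()` — the 64 drugs with positive signals under the
#'   four-method rule, with their printed disproportionality statistics and
#'   therapeutic categories.
#' * `dia_tto_reference()` — per-drug time-to-onset summaries (n, median,
#'   quartiles).
#'
#' These are published aggregate statistics, not raw reports: the package
#' uses them to exercise its arithmetic (shares, tiers, cross-tabs), not as
#' fitted model inputs.
#'
#' @return a data.frame.
#' @name reference_tables
NULL

.read_extdata <- function(file) {
  utils::read.csv(system.file("extdata", file, package = "pvsignal"),
                  stringsAsFactors = FALSE)
}

#' @rdname reference_tables
#' @export
dia_baseline_counts <- function() .read_extdata("dia_baseline_counts.csv")

#' @rdname reference_tables
#' @export
dia_signal_reference <- function() .read_extdata("dia_signal_reference.csv")

#' @rdname reference_tables
#' @export
dia_tto_reference <- function() .read_extdata("dia_tto_reference.csv")
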