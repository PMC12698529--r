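#' Build the 2x2 contingency table for one drug-event pair
#'
#' Cells follow the standard pharmacovigilance layout on de-duplicated
#' cases: `a` = cases with the drug and the event, `b` = drug without the
#' event, `c` = event without the drug, `d` = neither; `N = a+b+c+d` equals
#' the total de-duplicated case count.
#'
#' @param index a `drug_case_index`.
#' @param drug_name indexed drug.
#' @return a `contingency` list with integer `a`, `b`, `c`, `d`, `n`.
#' @export
build_contingency <- function(index, drug_name) {
  stopifnot(inherits(index, "drug_case_index"))
  ids <- index$pairs$primaryid[index$pairs$drug_name == drug_name]
  if (length(ids) == 0L) stop("drug not indexed: ", drug_name)
  a <- length(intersect(ids, index$event_cases))
  b <- length(ids) - a
  c_ <- length(index$event_cases) - a
  d <- length(index$all_cases) - a - b - c_
  contingency(a, b, c_, d)
}

#' Construct a contingency table from its four cells
#' @param a,b,c,d non-negative integer cell counts.
#' @return a `contingency` object.
#' @export
contingency <- function(a, b, c, d) {
  cells <- c(a = a, b = b, c = c, d = d)
  stopifnot(all(cells >= 0), all(cells == round(cells)), sum(cells) > 0)
  structure(list(a = as.integer(a), b = as.integer(b), c = as.integer(c),
                 d = as.integer(d), n = as.integer(a + b + c + d)),
            class = "contingency")
}

#' Contingency cells for every indexed drug
#'
#' Vectorized counterpart of [build_contingency()] over the whole index.
#'
#' @param index a `drug_case_index`.
#' @return data.table with columns `drug_name`, `a`, `b`, `c`, `d`, `n`.
#' @export
contingency_all <- function(index) {
  stopifnot(inherits(index, "drug_case_index"))
  ev <- index$event_cases
  n_total <- length(index$all_cases)
  n_event <- length(ev)
  tab <- index$pairs[, .(n_drug = .N, a = sum(primaryid %in% ev)),
                     by = drug_name]
  tab[, `:=`(b = n_drug - a, c = n_event - a)]
  tab[, d := n_total - a - b - c]
  data.table::setorder(tab, drug_name)
  tab[, .(drug_name, a, b, c, d, n = n_total)]
}

.cells <- function(t) {
  if (!inherits(t, "contingency")) {
    stopifnot(all(c("a", "b", "c", "d") %in% names(t)))
  }
  # double precision: cell products overflow 32-bit integers at FAERS scale
  list(a = as.numeric(t$a), b = as.numeric(t$b),
       c = as.numeric(t$c), d = as.numeric(t$d))
}

#' Reporting odds ratio with Woolf confidence interval
#'
#' `ROR = ad/bc`; the interval is log-normal:
#' `exp(ln ROR +/- z * sqrt(1/a + 1/b + 1/c + 1/d))`. With any zero cell the
#' statistic is undefined and `NA` is returned unless the Haldane-Anscombe
#' +0.5 correction is enabled.
#'
#' @param t a `contingency` (or data.frame of cell vectors, vectorized).
#' @param z normal quantile for the interval (default 1.96).
#' @param haldane add 0.5 to every cell when any cell is zero (off by
#'   default).
#' @return data.frame with `ror`, `ror_lo`, `ror_hi`.
#' @export
compute_ror <- function(t, z = 1.96, haldane = FALSE) {
  x <- .cells(t)
  a <- x$a; b <- x$b; c_ <- x$c; d <- x$d
  zero <- a == 0 | b == 0 | c_ == 0 | d == 0
  if (haldane) {
    a <- a + 0.5 * zero; b <- b + 0.5 * zero
    c_ <- c_ + 0.5 * zero; d <- d + 0.5 * zero
    zero <- rep(FALSE, length(a))
  }
  ror <- (a * d) / (b * c_)
  se <- sqrt(1 / a + 1 / b + 1 / c_ + 1 / d)
  lo <- exp(log(ror) - z * se)
  hi <- exp(log(ror) + z * se)
  ror[zero] <- lo[zero] <- hi[zero] <- NA_real_
  data.frame(ror = ror, ror_lo = lo, ror_hi = hi)
}

#' Proportional reporting ratio and chi-square
#'
#' `PRR = [a/(a+b)] / [c/(c+d)]`; the accompanying statistic is the Pearson
#' chi-square on the 2x2, `N(ad-bc)^2 / ((a+b)(c+d)(a+c)(b+d))`, without
#' continuity correction by default (Yates behind a flag). PRR is undefined
#' (`NA`) when `c = 0`.
#'
#' @param t a `contingency` (or data.frame of cell vectors, vectorized).
#' @param yates apply Yates' continuity correction to the chi-square.
#' @return data.frame with `prr`, `chi2`.
#' @export
compute_prr <- function(t, yates = FALSE) {
  x <- .cells(t)
  a <- x$a; b <- x$b; c_ <- x$c; d <- x$d
  n <- a + b + c_ + d
  prr <- (a / (a + b)) / (c_ / (c_ + d))
  prr[c_ == 0 | a + b == 0] <- NA_real_
  dev <- abs(a * d - b * c_)
  if (yates) dev <- pmax(0, dev - n / 2)
  chi2 <- n * dev^2 / ((a + b) * (c_ + d) * (a + c_) * (b + d))
  chi2[(a + b) == 0 | (c_ + d) == 0 | (a + c_) == 0 | (b + d) == 0] <- NA_real_
  data.frame(prr = prr, chi2 = chi2)
}

#' BCPNN information component
#'
#' The information component is a shrunk log2 observed-to-expected ratio:
#' with expected count `E = (a+b)(a+c)/N`,
#' `IC = log2((a + 0.5) / (E + 0.5))`, and its lower 2.5% credibility bound
#' uses the Noren closed-form approximation
#' `IC025 = IC - 3.3 (a+0.5)^-1/2 - 2 (a+0.5)^-3/2`. The 0.5 shrinkage makes
#' every cell configuration safe. An unshrunk variant
#' `log2(aN / ((a+b)(a+c)))` is available behind a flag.
#'
#' @param t a `contingency` (or data.frame of cell vectors, vectorized).
#' @param shrunk use the 0.5-shrunk estimator (default TRUE).
#' @return data.frame with `ic`, `ic025` (`ic025` is `NA` in the unshrunk
#'   variant, which has no closed-form bound here).
#' @export
compute_ic <- function(t, shrunk = TRUE) {
  x <- .cells(t)
  a <- x$a; b <- x$b; c_ <- x$c; d <- x$d
  n <- a + b + c_ + d
  e <- (a + b) * (a + c_) / n
  if (shrunk) {
    ic <- log2((a + 0.5) / (e + 0.5))
    ic025 <- ic - 3.3 * (a + 0.5)^(-0.5) - 2 * (a + 0.5)^(-1.5)
  } else {
    ic <- log2(a * n / ((a + b) * (a + c_)))
    ic025 <- rep(NA_real_, length(a))
  }
  data.frame(ic = ic, ic025 = ic025)
}

#' Expected count under independence
#' @param t a `contingency` or cell data.frame.
#' @return numeric `E = (a+b)(a+c)/N`.
#' @export
expected_count <- function(t) {
  x <- .cells(t)
  (x$a + x$b) * (x$a + x$c) / (x$a + x$b + x$c + x$d)
}

#' Evaluate the four-method positivity rule for one drug
#'
#' Default criteria, configurable via `thresholds`:
#' ROR: `a >= 3` and lower CI bound `> 1`; PRR: `a >= 3`, `PRR >= 2`,
#' `chi2 >= 4`; BCPNN: `IC025 > 0`; MGPS: `EBGM05 > 2`. A drug is a positive
#' signal only when all four hold simultaneously. An undefined statistic
#' makes its flag FALSE.
#'
#' @param t a `contingency`.
#' @param stats one-row data.frame carrying `ror_lo`, `prr`, `chi2`,
#'   `ic025`, `ebgm05` (as produced by the compute_* functions).
#' @param thresholds see [signal_thresholds()].
#' @return one-row data.frame with per-method flags and `positive`.
#' @export
evaluate_signal <- function(t, stats, thresholds = signal_thresholds()) {
  a <- .cells(t)$a
  flags <- .signal_flags(a, stats$ror_lo, stats$prr, stats$chi2,
                         stats$ic025, stats$ebgm05, thresholds)
  cbind(flags, positive = flags$ror_pos & flags$prr_pos &
          flags$bcpnn_pos & flags$mgps_pos)
}

.signal_flags <- function(a, ror_lo, prr, chi2, ic025, ebgm05, th) {
  isT <- function(x) !is.na(x) & x
  data.frame(
    ror_pos = isT(a >= th$min_a & ror_lo > th$ror_lo),
    prr_pos = isT(a >= th$min_a & prr >= th$prr & chi2 >= th$chi2),
    bcpnn_pos = isT(ic025 > th$ic025),
    mgps_pos = isT(ebgm05 > th$ebgm05)
  )
}

#' Positivity thresholds for the four disproportionality methods
#'
#' The defaults are the conventional criteria used across FAERS
#' disproportionality studies; every value can be overridden.
#'
#' @param min_a minimum co-report count for ROR/PRR (default 3).
#' @param ror_lo lower ROR CI bound must exceed this (default 1).
#' @param prr minimum PRR (default 2).
#' @param chi2 minimum chi-square (default 4).
#' @param ic025 IC025 must exceed this (default 0).
#' @param ebgm05 EBGM05 must exceed this (default 2).
#' @return a named list of thresholds.
#' @export
signal_thresholds <- function(min_a = 3, ror_lo = 1, prr = 2, chi2 = 4,
                              ic025 = 0, ebgm05 = 2) {
  stopifnot(min_a >= 0, prr > 0, chi2 >= 0, ebgm05 > 0)
  list(min_a = min_a, ror_lo = ror_lo, prr = prr, chi2 = chi2,
       ic025 = ic025, ebgm05 = ebgm05)
}

#' Fisher exact p-values with Bonferroni adjustment (volcano statistics)
#'
#' Two-sided Fisher exact test per table, with `p_adjusted = min(1, m p)`
#' where `m` is the number of drugs tested, and the natural-log ROR used as
#' the volcano x-axis.
#'
#' @param cells data.frame with columns `a`, `b`, `c`, `d` (one row per
#'   drug).
#' @param m Bonferroni family size (default: number of rows).
#' @return data.frame with `fisher_p`, `p_adjusted`, `log_ror`.
#' @export
fisher_volcano <- function(cells, m = nrow(cells)) {
  stopifnot(nrow(cells) >= 1L)
  p <- vapply(seq_len(nrow(cells)), function(i) {
    stats::fisher.test(matrix(c(cells$a[i], cells$b[i],
                                cells$c[i], cells$d[i]),
                              nrow = 2, byrow = TRUE))$p.value
  }, numeric(1))
  log_ror <- log((cells$a * cells$d) / (cells$b * cells$c))
  log_ror[cells$a == 0 | cells$b == 0 | cells$c == 0 | cells$d == 0] <- NA_real_
  data.frame(fisher_p = p, p_adjusted = pmin(1, m * p), log_ror = log_ror)
}

#' Full disproportionality table for every indexed drug
#'
#' Builds all 2x2 tables, fits the gamma-Poisson shrinkage prior across
#' them (unless supplied), and returns all four statistics with interval
#' bounds, Fisher/Bonferroni p-values, per-method flags and the joint
#' positivity verdict — the tidy per-drug result table of the pipeline.
#'
#' @param index a `drug_case_index`.
#' @param thresholds see [signal_thresholds()].
#' @param prior optional pre-fit `mgps_prior`; fitted on the index's tables
#'   when `NULL`.
#' @param min_cases drop drugs with fewer total cases than this before
#'   testing (default 1 = keep all).
#' @param fisher compute Fisher exact p-values (TRUE; the exact test
#'   dominates runtime on large drug panels).
#' @param ... passed to [compute_ror()] / [compute_prr()] /
#'   [compute_ic()] (e.g. `haldane`, `yates`).
#' @return data.frame, one row per drug, with cells, `ror`/`ror_lo`/
#'   `ror_hi`, `prr`/`chi2`, `ic`/`ic025`, `ebgm`/`ebgm05`, `fisher_p`/
#'   `p_adjusted`, per-method flags and `positive`.
#' @export
signal_table <- function(index, thresholds = signal_thresholds(),
                         prior = NULL, min_cases = 1L, fisher = TRUE, ...) {
  cells <- contingency_all(index)
  cells <- cells[(a + b) >= min_cases]
  if (nrow(cells) == 0L) stop("no drugs to evaluate")
  dots <- list(...)
  ror <- compute_ror(cells, haldane = isTRUE(dots$haldane))
  prr <- compute_prr(cells, yates = isTRUE(dots$yates))
  ic <- compute_ic(cells)
  if (is.null(prior)) prior <- fit_mgps_prior(cells)
  eb <- compute_ebgm(cells, prior)
  if (fisher) {
    fv <- fisher_volcano(cells)
  } else {
    fv <- data.frame(fisher_p = rep(NA_real_, nrow(cells)),
                     p_adjusted = NA_real_, log_ror = NA_real_)
  }
  flags <- .signal_flags(cells$a, ror$ror_lo, prr$prr, prr$chi2,
                         ic$ic025, eb$ebgm05, thresholds)
  out <- cbind(as.data.frame(cells), ror, prr, ic, eb, fv, flags)
  out$positive <- flags$ror_pos & flags$prr_pos & flags$bcpnn_pos &
    flags$mgps_pos
  attr(out, "prior") <- prior
  out
}
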