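#' Extract time-to-onset records
#'
#' Time-to-onset is the whole-day difference between the adverse-event date
#' and the earliest Primary-Suspect therapy start date for the drug within
#' the case. Only day-precision dates qualify; records with missing dates,
#' partial precision, or an event before the start are excluded, with
#' exclusion counts attached.
#'
#' @param case_set a `faers_case_set`.
#' @param drug_name optional single drug; default extracts for all drugs.
#' @param event_ids optional restriction to target-event cases.
#' @param role_filter drug roles defining exposure (default PS).
#' @return data.frame with `primaryid`, `drug_name`, `days`; exclusion
#'   counters in attribute `exclusions`.
#' @export
extract_tto <- function(case_set, drug_name = NULL, event_ids = NULL,
                        role_filter = "PS") {
  dr <- case_set$drugs[role %in% role_filter]
  if (!is.null(drug_name)) {
    dr <- dr[dr$drug_name %in% normalize_drug_name(drug_name)]
  }
  if (!is.null(event_ids)) dr <- dr[primaryid %in% event_ids]
  # earliest day-precision start per case x drug
  dr <- dr[!is.na(start_ord) & start_precision == "day"]
  data.table::setorderv(dr, c("primaryid", "drug_name", "start_ord"))
  dr <- dr[!duplicated(dr[, .(primaryid, drug_name)])]
  cs <- case_set$cases[, .(primaryid, event_dt, event_precision)]
  j <- merge(dr, cs, by = "primaryid", sort = FALSE)
  n0 <- nrow(j)
  ok_event <- !is.na(j$event_dt) & j$event_precision == "day"
  j <- j[ok_event]
  days <- as.integer(j$event_dt - j$start_dt)
  neg <- days < 0
  out <- data.frame(primaryid = j$primaryid[!neg],
                    drug_name = j$drug_name[!neg],
                    days = days[!neg])
  out <- out[order(out$primaryid, out$drug_name), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "exclusions") <- c(no_event_date = n0 - nrow(j),
                               negative_days = sum(neg))
  out
}

#' Summarize a time-to-onset distribution
#'
#' Quartiles use Tukey's median-of-halves convention (the median belongs to
#' both halves), so a single record has median = Q1 = Q3. The histogram uses
#' half-open bins `[lo, hi)`; the defaults are 30-day steps to 240 days,
#' then 240-360 and beyond 360.
#'
#' @param records output of [extract_tto()], or a numeric vector of days.
#' @param breaks bin edges (finite left edges; Inf appended).
#' @return list with `n`, `median`, `q1`, `q3`, `mean` and a `histogram`
#'   data.frame (`bin`, `n`, `pct`).
#' @export
summarize_tto <- function(records,
                          breaks = c(seq(0, 240, by = 30), 360, Inf)) {
  days <- if (is.numeric(records)) records else records$days
  days <- days[!is.na(days)]
  if (length(days) == 0L) {
    return(list(n = 0L, median = NA_real_, q1 = NA_real_, q3 = NA_real_,
                mean = NA_real_, histogram = data.frame()))
  }
  fn <- stats::fivenum(days)
  if (is.finite(breaks[length(breaks)])) breaks <- c(breaks, Inf)
  lab <- paste0("[", head(breaks, -1), ",", breaks[-1], ")")
  cnt <- table(cut(days, breaks = breaks, right = FALSE, labels = lab))
  hist <- data.frame(bin = names(cnt), n = as.integer(cnt),
                     pct = share_pct(as.integer(cnt), length(days)),
                     row.names = NULL)
  list(n = length(days), median = fn[3], q1 = fn[2], q3 = fn[4],
       mean = mean(days), histogram = hist)
}

#' Fit a Weibull model to onset latencies
#'
#' Maximum-likelihood Weibull fit of onset days. The Weibull support is the
#' positive reals, so zero-day onsets (same-day events, which do occur for
#' topical agents) are shifted by +0.5 day for the likelihood only. Wald
#' confidence intervals are computed on the log scale of both parameters;
#' the median latency is `scale * log(2)^(1/shape)`.
#'
#' @param records output of [extract_tto()] or numeric vector of days.
#' @param min_n minimum number of distinct positive values required
#'   (default 10).
#' @param conf_level CI level (default 0.95).
#' @return a `weibull_fit`: list with `shape`, `scale`, `ci_shape`,
#'   `ci_scale`, `median_days`, `n`.
#' @export
fit_weibull <- function(records, min_n = 10L, conf_level = 0.95) {
  days <- if (is.numeric(records)) records else records$days
  days <- days[!is.na(days)]
  x <- ifelse(days == 0, 0.5, days)
  if (length(unique(x[x > 0])) < min_n) {
    stop("Weibull fit needs at least ", min_n, " distinct positive values")
  }
  if (length(unique(x)) == 1L) stop("all onset values identical")
  fit <- fitdistrplus::fitdist(as.numeric(x), "weibull")
  if (any(!is.finite(fit$estimate))) stop("Weibull fit did not converge")
  shape <- unname(fit$estimate["shape"])
  scale <- unname(fit$estimate["scale"])
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  se <- fit$sd
  ci <- function(est, s) {
    if (is.null(s) || any(is.na(s))) return(c(NA_real_, NA_real_))
    exp(log(est) + c(-1, 1) * z * s / est)  # Wald on log scale
  }
  structure(list(shape = shape, scale = scale,
                 ci_shape = ci(shape, unname(se["shape"])),
                 ci_scale = ci(scale, unname(se["scale"])),
                 median_days = scale * log(2)^(1 / shape),
                 n = length(x), loglik = fit$loglik),
            class = "weibull_fit")
}

#' @export
print.weibull_fit <- function(x, ...) {
  cat(sprintf(paste0("<weibull_fit> shape %.3f (%.3f-%.3f), scale %.1f ",
                     "(%.1f-%.1f) days; median %.1f days (n=%d)\n"),
              x$shape, x$ci_shape[1], x$ci_shape[2],
              x$scale, x$ci_scale[1], x$ci_scale[2], x$median_days, x$n))
  invisible(x)
}

#' Compare onset-time distributions between two groups
#'
#' Two-sided Wilcoxon rank-sum test: exact enumeration when the combined
#' sample size is at most 12 and there are no ties, otherwise the normal
#' approximation with tie and continuity corrections.
#'
#' @param g1,g2 numeric vectors of onset days (or [extract_tto()] outputs).
#' @return list with `statistic` (W), `p_value`, `method`, and per-group
#'   `n`, `mean`, `median`.
#' @export
compare_tto_groups <- function(g1, g2) {
  x <- if (is.numeric(g1)) g1 else g1$days
  y <- if (is.numeric(g2)) g2 else g2$days
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  if (length(x) == 0L || length(y) == 0L) stop("both groups must be non-empty")
  ties <- anyDuplicated(c(x, y)) > 0
  exact <- (length(x) + length(y) <= 12) && !ties
  wt <- suppressWarnings(
    stats::wilcox.test(x, y, exact = exact, correct = !exact))
  list(statistic = unname(wt$statistic), p_value = wt$p.value,
       method = if (exact) "exact" else "normal approximation",
       n1 = length(x), n2 = length(y),
       mean1 = mean(x), mean2 = mean(y),
       median1 = stats::median(x), median2 = stats::median(y))
}

#' Per-drug time-to-onset summary table
#'
#' Mirrors the standard per-drug latency report: case count, median and
#' quartiles, plus Weibull shape/scale (with CIs) for drugs with enough
#' usable records.
#'
#' @param case_set a `faers_case_set`.
#' @param event_ids target-event primaryids.
#' @param min_fit_n minimum records for a Weibull fit (default 10).
#' @param role_filter drug roles defining exposure (default PS).
#' @return data.frame with one row per drug, sorted by descending median.
#' @export
tto_by_drug <- function(case_set, event_ids, min_fit_n = 10L,
                        role_filter = "PS") {
  rec <- extract_tto(case_set, event_ids = event_ids,
                     role_filter = role_filter)
  if (nrow(rec) == 0L) return(data.frame())
  sp <- split(rec$days, rec$drug_name)
  rows <- lapply(names(sp), function(dn) {
    s <- summarize_tto(sp[[dn]])
    fit <- if (length(unique(pmax(sp[[dn]], 0.5))) >= min_fit_n) {
      tryCatch(fit_weibull(sp[[dn]], min_n = min_fit_n),
               error = function(e) NULL)
    }
    data.frame(drug_name = dn, n = s$n, median = s$median, q1 = s$q1,
               q3 = s$q3, mean = s$mean,
               shape = if (is.null(fit)) NA_real_ else fit$shape,
               shape_lo = if (is.null(fit)) NA_real_ else fit$ci_shape[1],
               shape_hi = if (is.null(fit)) NA_real_ else fit$ci_shape[2],
               scale = if (is.null(fit)) NA_real_ else fit$scale,
               scale_lo = if (is.null(fit)) NA_real_ else fit$ci_scale[1],
               scale_hi = if (is.null(fit)) NA_real_ else fit$ci_scale[2],
               weibull_median = if (is.null(fit)) NA_real_ else fit$median_days)
  })
  out <- do.call(rbind, rows)
  out[order(-out$median, out$drug_name), , drop = FALSE]
}
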