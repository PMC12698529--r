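#' Age band classification
#'
#' Bands `<18`, `18-44`, `45-64`, `>=65`: closed on the left, open on the
#' right, with `>=65` closed below.
#'
#' @param age_years numeric ages.
#' @return character vector of band labels (`NA` for missing age).
#' @export
age_band <- function(age_years) {
  as.character(cut(age_years, breaks = c(-Inf, 18, 45, 65, Inf),
                   right = FALSE,
                   labels = c("<18", "18-44", "45-64", ">=65")))
}

#' Baseline descriptive summary of target-event cases
#'
#' Frequencies and percentages for sex, reporting-year bins, reporting
#' region, reporter occupation, severity and outcome codes, plus mean/SD and
#' median/IQR for age and weight. Percentages are computed over the
#' event-case total and rounded half-up to 2 decimals; raw counts are
#' retained.
#'
#' @param case_set a `faers_case_set`.
#' @param event_ids primaryids to summarize (default: all cases).
#' @param year_breaks integer years splitting the reporting-period bins.
#' @return list with `categorical` (block, level, n, pct) and `continuous`
#'   (block, n_known, mean, sd, median, q1, q3) data.frames, and `n_total`.
#' @export
baseline_summary <- function(case_set, event_ids = NULL,
                             year_breaks = c(2011, 2016, 2021)) {
  cs <- case_set$cases
  if (!is.null(event_ids)) cs <- cs[primaryid %in% event_ids]
  n_total <- nrow(cs)
  stopifnot(n_total > 0)

  cat_block <- function(block, values) {
    values <- ifelse(is.na(values) | !nzchar(values), "unknown", values)
    tab <- sort(table(values), decreasing = TRUE)
    data.frame(block = block, level = names(tab), n = as.integer(tab),
               pct = share_pct(as.integer(tab), n_total),
               stringsAsFactors = FALSE, row.names = NULL)
  }
  year <- as.integer(format(cs$fda_dt, "%Y"))
  yb <- sort(year_breaks)
  ylab <- cut(year, breaks = c(-Inf, yb, Inf), right = FALSE,
              labels = c(paste0("<", yb[1]),
                         paste(head(yb, -1), yb[-1] - 1, sep = "-"),
                         paste0(">=", yb[length(yb)])))
  categorical <- rbind(
    cat_block("sex", cs$sex),
    cat_block("reporting_year", as.character(ylab)),
    cat_block("region", cs$country),
    cat_block("reporter_occupation", cs$reporter_occupation),
    cat_block("severity", ifelse(cs$serious, "serious", "non-serious"))
  )
  if (nrow(case_set$outcomes)) {
    oc <- case_set$outcomes[primaryid %in% cs$primaryid]
    tab <- sort(table(oc$outc_cod), decreasing = TRUE)
    categorical <- rbind(categorical, data.frame(
      block = "outcome", level = names(tab), n = as.integer(tab),
      pct = share_pct(as.integer(tab), n_total), row.names = NULL))
  }

  cont_block <- function(block, x) {
    x <- x[!is.na(x)]
    data.frame(block = block, n_known = length(x),
               mean = mean(x), sd = stats::sd(x),
               median = stats::median(x),
               q1 = unname(stats::quantile(x, 0.25)),
               q3 = unname(stats::quantile(x, 0.75)))
  }
  continuous <- rbind(cont_block("age_years", cs$age_years),
                      cont_block("weight_kg", cs$weight_kg))
  list(categorical = categorical, continuous = continuous, n_total = n_total)
}

#' Stratified disproportionality analysis
#'
#' Recomputes the per-drug 2x2 tables within each demographic stratum using
#' stratum-restricted denominators (both the drug and comparator cases come
#' from the stratum), then applies the four-method rule and a Bonferroni
#' adjustment whose family size is the number of drugs evaluated within the
#' stratum. Cases missing the stratification field are excluded from that
#' stratification. A drug "loses significance" when its raw Fisher p is
#' below `alpha` but the adjusted p is not.
#'
#' @param case_set a `faers_case_set`.
#' @param event_ids target-event primaryids.
#' @param by `"sex"` or `"age"`.
#' @param thresholds see [signal_thresholds()].
#' @param prior optional shared `mgps_prior`; by default each stratum fits
#'   its own across its drug tables.
#' @param min_cases per-drug minimum case count within the stratum
#'   (default 3; tiny strata cells are uninformative and slow the exact
#'   test).
#' @param alpha significance level for the lost-significance flag.
#' @param role_filter drug roles indexed (default PS).
#' @return data.frame of per-drug results with a leading `stratum` column
#'   and a `lost_significance` flag.
#' @export
stratified_signals <- function(case_set, event_ids, by = c("sex", "age"),
                               thresholds = signal_thresholds(),
                               prior = NULL, min_cases = 3L, alpha = 0.05,
                               role_filter = "PS") {
  by <- match.arg(by)
  cs <- case_set$cases
  strat <- switch(by,
                  sex = ifelse(cs$sex %in% c("F", "M"), cs$sex, NA_character_),
                  age = age_band(cs$age_years))
  out <- list()
  for (lev in sort(unique(strat[!is.na(strat)]))) {
    ids <- cs$primaryid[!is.na(strat) & strat == lev]
    sub <- subset_cases(case_set, ids)
    ev <- intersect(event_ids, ids)
    if (length(ev) == 0L) next
    idx <- build_drug_case_index(sub, ev, role_filter = role_filter)
    if (nrow(idx$pairs) == 0L) next
    st <- signal_table(idx, thresholds = thresholds, prior = prior,
                       min_cases = min_cases)
    st$p_adjusted <- pmin(1, nrow(st) * st$fisher_p)
    st$lost_significance <- st$fisher_p < alpha & st$p_adjusted >= alpha
    out[[lev]] <- cbind(stratum = lev, st)
  }
  if (length(out) == 0L) return(data.frame())
  do.call(rbind, c(out, make.row.names = FALSE))
}

#' Restrict a case set to a subset of cases
#' @param case_set a `faers_case_set`.
#' @param ids primaryids to keep.
#' @return the filtered `faers_case_set`.
#' @export
subset_cases <- function(case_set, ids) {
  structure(list(cases = case_set$cases[primaryid %in% ids],
                 drugs = case_set$drugs[primaryid %in% ids],
                 reactions = case_set$reactions[primaryid %in% ids],
                 outcomes = case_set$outcomes[primaryid %in% ids],
                 log = case_set$log),
            class = "faers_case_set")
}

#' Classify drugs into IC025 risk tiers
#'
#' High risk: `IC025 > 3`; medium: `1.5 < IC025 <= 3`; low: `IC025 <= 1.5`
#' (boundary values fall in the lower tier). Missing IC025 leaves a drug
#' unclassified.
#'
#' @param ic025 numeric vector of IC025 values, or a data.frame with an
#'   `ic025` column.
#' @return list with `tier` (character vector: high/medium/low/NA) and
#'   `counts` (named integer vector over the three tiers).
#' @export
classify_risk_tier <- function(ic025) {
  if (is.data.frame(ic025)) ic025 <- ic025$ic025
  tier <- ifelse(is.na(ic025), NA_character_,
                 ifelse(ic025 > 3, "high",
                        ifelse(ic025 > 1.5, "medium", "low")))
  counts <- c(high = sum(tier == "high", na.rm = TRUE),
              medium = sum(tier == "medium", na.rm = TRUE),
              low = sum(tier == "low", na.rm = TRUE))
  list(tier = tier, counts = counts)
}

#' Per-PT drug reporting shares
#'
#' For each preferred term of the query, computes the share of that PT's
#' cases attributable to each Primary-Suspect drug (a case may carry several
#' PS drugs, so shares within a PT sum to at most 100% times the mean PS
#' count). Returns the top `k` drugs per PT.
#'
#' @param case_set a `faers_case_set`.
#' @param smq an `smq_term_list`.
#' @param k number of top drugs per PT (default 10).
#' @param role_filter drug roles counted (default PS).
#' @return data.frame with `pt`, `drug_name`, `n`, `n_pt_cases`, `share`
#'   (percent, half-up 2 dp).
#' @export
pt_level_distribution <- function(case_set, smq, k = 10L,
                                  role_filter = "PS") {
  key <- tolower(smq$pts)
  rx <- case_set$reactions[tolower(pt) %in% key]
  if (nrow(rx) == 0L) return(data.frame())
  rx <- data.table::copy(rx)[, pt := smq$pts[match(tolower(pt), key)]]
  dr <- unique(case_set$drugs[role %in% role_filter,
                              .(primaryid, drug_name)])
  j <- merge(rx, dr, by = "primaryid", allow.cartesian = TRUE)
  npt <- rx[, .(n_pt_cases = data.table::uniqueN(primaryid)), by = pt]
  cnt <- j[, .(n = data.table::uniqueN(primaryid)), by = .(pt, drug_name)]
  cnt <- merge(cnt, npt, by = "pt")
  cnt[, share := share_pct(n, n_pt_cases[1]), by = pt]
  data.table::setorder(cnt, pt, -n, drug_name)
  as.data.frame(cnt[, head(.SD, k), by = pt])
}

#' Cross-tabulate positive signals against label documentation
#'
#' Partitions the positive-signal drugs by whether the event is documented
#' in the official prescribing-information annotation supplied by the user;
#' drugs without an annotation row are counted as `unknown`. Percentages are
#' over the positive-drug total, half-up to 1 decimal.
#'
#' @param positive_drugs character vector of positive-signal drug names.
#' @param annotations data.frame with columns `drug_name` and `documented`
#'   (logical or yes/no strings).
#' @return data.frame with `status` (documented/undocumented/unknown), `n`,
#'   `pct`.
#' @export
label_crosscheck <- function(positive_drugs, annotations) {
  stopifnot(all(c("drug_name", "documented") %in% names(annotations)))
  drugs <- normalize_drug_name(positive_drugs)
  key <- normalize_drug_name(annotations$drug_name)
  doc <- annotations$documented
  if (!is.logical(doc)) doc <- tolower(as.character(doc)) %in% c("yes", "true", "y", "1")
  hit <- match(drugs, key)
  status <- ifelse(is.na(hit), "unknown",
                   ifelse(doc[hit], "documented", "undocumented"))
  lv <- c("documented", "undocumented", "unknown")
  n <- vapply(lv, function(s) sum(status == s), integer(1))
  out <- data.frame(status = lv, n = n,
                    pct = share_pct(n, length(drugs), digits = 1))
  out[out$n > 0 | out$status != "unknown", , drop = FALSE]
}
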