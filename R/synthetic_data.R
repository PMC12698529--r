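#' Configuration for the synthetic spontaneous-report generator
#'
#' Defaults emulate the demographic and reporting structure of large FAERS
#' hair-loss case series: predominantly female reporters (76.82%, 13%
#' unknown sex), adult ages (mean 53.84, SD 16.28 years, 41.42% missing),
#' mostly-missing weights, consumer-dominated reporter occupations,
#' US-dominated reporting regions, a 2004-2024 receipt-date distribution
#' peaking in 2016-2020, and a background target-event reporting rate of
#' 0.8% per case (the FAERS-wide alopecia share). Each synthetic case
#' carries one Primary-Suspect drug; per-drug relative reporting-rate
#' multipliers plant known signals and per-drug Weibull latencies plant
#' known onset distributions.
#'
#' @param n_cases number of de-duplicated cases to simulate.
#' @param n_drugs number of distinct drugs.
#' @param n_background_pts size of the background PT vocabulary.
#' @param effect_map named numeric vector mapping drug names to relative
#'   reporting rates (RR >= 0) for the target event; unnamed drugs get RR 1.
#' @param event_base_rate baseline probability that a case reports the
#'   target event; the per-drug probability is
#'   `min(1, event_base_rate * RR)`.
#' @param female_share,male_share probabilities of female/male sex; the
#'   remainder is recorded as unknown.
#' @param age_mean,age_sd age distribution in years (truncated to 1-100).
#' @param missing_age_rate,missing_weight_rate missingness probabilities.
#' @param serious_rate probability a case carries outcome codes.
#' @param tto_params per-drug Weibull onset parameters: data.frame with
#'   `drug_name`, `shape`, `scale`; drugs not listed use
#'   `default_tto = c(shape, scale)`.
#' @param default_tto length-2 numeric, default Weibull (shape, scale) in
#'   days.
#' @param duplicate_rate fraction of cases that also emit an older report
#'   version (same caseid, earlier FDA_DT, lower primaryid).
#' @param missing_date_rate probability that a therapy start date is blank.
#' @param partial_date_rate probability that an emitted date is truncated
#'   to month or year precision.
#' @param polypharmacy_rate probability that a case carries additional
#'   non-PS (concomitant/secondary) drug entries.
#' @param seed integer seed; identical configs generate identical output.
#' @return a validated `synthetic_config`.
#' @export
synthetic_config <- function(n_cases = 10000L,
                             n_drugs = 20L,
                             n_background_pts = 100L,
                             effect_map = NULL,
                             event_base_rate = 0.008,
                             female_share = 0.7682,
                             male_share = 0.1018,
                             age_mean = 53.84,
                             age_sd = 16.28,
                             missing_age_rate = 0.4142,
                             missing_weight_rate = 0.7153,
                             serious_rate = 0.4669,
                             tto_params = NULL,
                             default_tto = c(1.2, 150),
                             duplicate_rate = 0.05,
                             missing_date_rate = 0.10,
                             partial_date_rate = 0.05,
                             polypharmacy_rate = 0,
                             seed = 1L) {
  cfg <- list(n_cases = as.integer(n_cases), n_drugs = as.integer(n_drugs),
              n_background_pts = as.integer(n_background_pts),
              effect_map = effect_map, event_base_rate = event_base_rate,
              female_share = female_share, male_share = male_share,
              age_mean = age_mean, age_sd = age_sd,
              missing_age_rate = missing_age_rate,
              missing_weight_rate = missing_weight_rate,
              serious_rate = serious_rate,
              tto_params = tto_params, default_tto = default_tto,
              duplicate_rate = duplicate_rate,
              missing_date_rate = missing_date_rate,
              partial_date_rate = partial_date_rate,
              polypharmacy_rate = polypharmacy_rate,
              seed = as.integer(seed))
  probs <- c("event_base_rate", "female_share", "male_share",
             "missing_age_rate", "missing_weight_rate", "serious_rate",
             "duplicate_rate", "missing_date_rate", "partial_date_rate",
             "polypharmacy_rate")
  bad <- probs[vapply(probs, function(p) {
    v <- cfg[[p]]; !is.numeric(v) || v < 0 || v > 1
  }, logical(1))]
  if (cfg$female_share + cfg$male_share > 1) bad <- c(bad, "female_share+male_share")
  if (cfg$n_cases < 1L) bad <- c(bad, "n_cases")
  if (cfg$n_drugs < 1L) bad <- c(bad, "n_drugs")
  if (!is.null(effect_map) && (is.null(names(effect_map)) ||
                               any(effect_map < 0))) bad <- c(bad, "effect_map")
  if (any(cfg$default_tto <= 0) || length(cfg$default_tto) != 2L) {
    bad <- c(bad, "default_tto")
  }
  if (length(bad)) {
    stop("invalid synthetic_config field(s): ", paste(bad, collapse = ", "))
  }
  structure(cfg, class = "synthetic_config")
}

# deterministic helpers -----------------------------------------------

.fmt_date <- function(d) format(d, "%Y%m%d")

.truncate_dates <- function(s, p_partial) {
  n <- length(s)
  u <- runif(n)
  s[u < p_partial / 2] <- substr(s[u < p_partial / 2], 1, 6)   # month
  sel <- u >= p_partial / 2 & u < p_partial
  s[sel] <- substr(s[sel], 1, 4)                               # year
  s
}

#' Generate synthetic FAERS-style tables with known ground truth
#'
#' Emits the five quarterly tables (DEMO, DRUG, REAC, THER, OUTC) as
#' `raw_record_set`s, plus the ground truth used to generate them. Output is
#' a deterministic function of the configuration (including its seed).
#'
#' @param config a `synthetic_config`.
#' @return list with `tables` (named list of `raw_record_set`s) and `truth`
#'   (per-drug `rr`, per-drug Weibull `tto`, and the `duplicate_map` of
#'   caseid to the primaryid that de-duplication must retain).
#' @export
generate_reports <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(config$seed)

  n <- config$n_cases
  drugs <- sprintf("DRUG %03d", seq_len(config$n_drugs))
  if (!is.null(config$effect_map)) {
    extra <- setdiff(names(config$effect_map), drugs)
    if (length(extra) > config$n_drugs) stop("effect_map larger than n_drugs")
    drugs[seq_along(extra)] <- normalize_drug_name(extra)
  }
  rr <- setNames(rep(1, config$n_drugs), drugs)
  if (!is.null(config$effect_map)) {
    nm <- normalize_drug_name(names(config$effect_map))
    rr[nm] <- unname(config$effect_map)
  }
  tto <- data.frame(drug_name = drugs,
                    shape = config$default_tto[1],
                    scale = config$default_tto[2])
  if (!is.null(config$tto_params)) {
    nm <- normalize_drug_name(config$tto_params$drug_name)
    hit <- match(nm, tto$drug_name)
    tto$shape[hit] <- config$tto_params$shape
    tto$scale[hit] <- config$tto_params$scale
  }

  caseid <- as.character(10000000L + seq_len(n))
  primaryid <- paste0(caseid, "2")  # version 2 ids
  di <- sample.int(config$n_drugs, n, replace = TRUE)
  event <- runif(n) < pmin(1, config$event_base_rate * rr[di])

  # FDA receipt dates: year-bin weights emulating the 2004-2024 reporting
  # curve, uniform within bin
  bins <- list(2004:2010, 2011:2015, 2016:2020, 2021:2024)
  bi <- sample.int(4L, n, replace = TRUE,
                   prob = c(0.0751, 0.1622, 0.4826, 0.2800))
  year <- vapply(bins[bi], function(y) y[sample.int(length(y), 1L)],
                 numeric(1))
  fda <- as.Date(sprintf("%d-01-01", year)) + sample.int(365L, n, TRUE) - 1L
  delay <- pmin(365L, stats::rgeom(n, 1 / 60))
  event_dt <- fda - delay
  onset <- round(rweibull(n, tto$shape[di], tto$scale[di]))
  start_dt <- event_dt - onset

  sex <- sample(c("F", "M", NA), n, replace = TRUE,
                prob = c(config$female_share, config$male_share,
                         1 - config$female_share - config$male_share))
  age <- pmin(100, pmax(1, round(rnorm(n, config$age_mean, config$age_sd))))
  age_cod <- sample(c("YR", "MON", "DEC"), n, TRUE, prob = c(0.9, 0.05, 0.05))
  age_val <- ifelse(age_cod == "YR", age,
                    ifelse(age_cod == "MON", age * 12, age / 10))
  age_val <- as.character(age_val)
  age_val[runif(n) < config$missing_age_rate] <- NA
  age_cod[is.na(age_val)] <- NA
  wt <- round(rlnorm(n, log(72), 0.22), 1)
  wt_cod <- sample(c("KG", "LBS"), n, TRUE, prob = c(0.8, 0.2))
  wt_val <- as.character(ifelse(wt_cod == "LBS", round(wt / 0.4536, 1), wt))
  wt_val[runif(n) < config$missing_weight_rate] <- NA
  wt_cod[is.na(wt_val)] <- NA
  occp <- sample(c("CN", "MD", "PH", "LW", "OT", NA), n, TRUE,
                 prob = c(0.5588, 0.1365, 0.1192, 0.0870, 0.0668, 0.0317))
  country <- sample(c("US", "CA", "GB", "FR", "DE", "JP", "IT", "AU"), n,
                    TRUE, prob = c(0.7412, 0.0731, 0.0297, 0.0284, 0.0175,
                                   0.04, 0.03, 0.0301))

  demo <- data.table::data.table(
    primaryid = primaryid, caseid = caseid, caseversion = "2",
    fda_dt = .fmt_date(fda),
    event_dt = .truncate_dates(.fmt_date(event_dt),
                               config$partial_date_rate),
    age = age_val, age_cod = age_cod, sex = sex,
    wt = wt_val, wt_cod = wt_cod, occp_cod = occp,
    reporter_country = country)

  drug_rows <- data.table::data.table(
    primaryid = primaryid, caseid = caseid, drug_seq = "1",
    role_cod = "PS", drugname = drugs[di],
    route = sample(c("ORAL", "SUBCUTANEOUS", "INTRAVENOUS", NA), n, TRUE,
                   prob = c(0.45, 0.17, 0.16, 0.22)))
  if (config$polypharmacy_rate > 0) {
    extra_sel <- which(runif(n) < config$polypharmacy_rate)
    if (length(extra_sel)) {
      co <- data.table::data.table(
        primaryid = primaryid[extra_sel], caseid = caseid[extra_sel],
        drug_seq = "2",
        role_cod = sample(c("C", "SS", "I"), length(extra_sel), TRUE,
                          prob = c(0.6, 0.3, 0.1)),
        drugname = drugs[sample.int(config$n_drugs, length(extra_sel),
                                    TRUE)],
        route = NA)
      drug_rows <- rbind(drug_rows, co)
    }
  }

  start_str <- .truncate_dates(.fmt_date(start_dt), config$partial_date_rate)
  start_str[runif(n) < config$missing_date_rate] <- NA
  ther <- data.table::data.table(primaryid = primaryid, caseid = caseid,
                                 dsg_drug_seq = "1", start_dt = start_str)

  # reactions: target-event PT for event cases + 1-3 background PTs
  ev_pts <- alopecia_smq()$pts
  n_bg <- sample.int(3L, n, replace = TRUE)
  bg <- data.table::data.table(
    primaryid = rep(primaryid, n_bg),
    caseid = rep(caseid, n_bg),
    pt = sprintf("Background PT %03d",
                 sample.int(config$n_background_pts, sum(n_bg), TRUE)))
  tg <- data.table::data.table(
    primaryid = primaryid[event], caseid = caseid[event],
    pt = ev_pts[sample.int(length(ev_pts), sum(event), TRUE,
                           prob = c(0.6, rep(0.4 / (length(ev_pts) - 1),
                                             length(ev_pts) - 1)))])
  reac <- unique(rbind(bg, tg))

  serious <- runif(n) < config$serious_rate
  n_out <- ifelse(runif(n) < 0.2, 2L, 1L) * serious
  oc_codes <- c("OT", "HO", "DS", "LT", "DE", "RI", "CA")
  oc_prob <- c(0.6621, 0.1684, 0.0894, 0.0346, 0.0325, 0.0066, 0.0064)
  outc <- data.table::data.table(
    primaryid = rep(primaryid, n_out), caseid = rep(caseid, n_out),
    outc_cod = oc_codes[sample.int(7L, sum(n_out), TRUE, prob = oc_prob)])

  # duplicate versions: older report (version 1) with earlier FDA_DT,
  # sharing the caseid; de-duplication must retain version 2
  dup_sel <- which(runif(n) < config$duplicate_rate)
  if (length(dup_sel)) {
    old_pid <- paste0(caseid[dup_sel], "1")
    dup_demo <- demo[dup_sel]
    dup_demo[, `:=`(primaryid = old_pid, caseversion = "1",
                    fda_dt = .fmt_date(fda[dup_sel] -
                                         sample(30:300, length(dup_sel),
                                                TRUE)))]
    demo <- rbind(demo, dup_demo)
    dup_drug <- drug_rows[drug_rows$primaryid %in% primaryid[dup_sel]]
    dup_drug <- data.table::copy(dup_drug)[
      , primaryid := paste0(caseid, "1")]
    drug_rows <- rbind(drug_rows, dup_drug)
    dup_reac <- reac[reac$primaryid %in% primaryid[dup_sel]]
    dup_reac <- data.table::copy(dup_reac)[
      , primaryid := paste0(caseid, "1")]
    reac <- rbind(reac, dup_reac)
  }
  data.table::setorder(demo, caseid, primaryid)

  truth <- list(
    rr = rr,
    tto = tto,
    event = data.table::data.table(primaryid = primaryid,
                                   drug_name = drugs[di], event = event,
                                   onset_days = onset),
    duplicate_map = data.table::data.table(caseid = caseid,
                                           retained_primaryid = primaryid))
  list(tables = list(DEMO = new_raw_record_set("DEMO", demo),
                     DRUG = new_raw_record_set("DRUG", drug_rows),
                     REAC = new_raw_record_set("REAC", reac),
                     THER = new_raw_record_set("THER", ther),
                     OUTC = new_raw_record_set("OUTC", outc)),
       truth = truth)
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  }
}

.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' Run the full signal pipeline on generated tables
#'
#' Convenience wrapper used throughout validation: de-duplicates, assembles,
#' flags target cases against the packaged term list, indexes
#' Primary-Suspect drugs and returns the signal table.
#'
#' @param tables named list of `raw_record_set`s (DEMO/DRUG/REAC/THER/OUTC).
#' @param smq term list (default [alopecia_smq()]).
#' @param ... passed to [signal_table()].
#' @return list with `case_set`, `event_ids`, `index`, `signals`.
#' @export
run_signal_pipeline <- function(tables, smq = alopecia_smq(), ...) {
  demo <- deduplicate(tables$DEMO)
  case_set <- assemble_cases(demo, tables$DRUG, tables$REAC,
                             tables$THER, tables$OUTC)
  event_ids <- flag_event_cases(case_set, smq)
  index <- build_drug_case_index(case_set, event_ids)
  list(case_set = case_set, event_ids = event_ids, index = index,
       signals = signal_table(index, ...))
}

#' Packaged end-to-end funnel fixture with a known signal funnel
#'
#' A deterministic synthetic database engineered so that exactly 71 drugs
#' carry strong planted signals (relative reporting rate 25) among 500
#' drugs, of which 7 are on the bundled exclusion list of drugs indicated
#' for the condition — so the signal funnel runs 71 positives down to 64
#' after exclusion. Used by the end-to-end pipeline tests.
#'
#' @param n_cases fixture size (default 50000 cases).
#' @return list with `tables`, `truth`, `planted` (71 drug names),
#'   `exclusion_list` (7 of them), and the `config` used.
#' @export
make_funnel_fixture <- function(n_cases = 50000L) {
  planted <- sprintf("SIGNAL DRUG %03d", 1:71)
  cfg <- synthetic_config(
    n_cases = n_cases, n_drugs = 500L,
    effect_map = setNames(rep(25, 71), planted),
    seed = 913L)
  g <- generate_reports(cfg)
  list(tables = g$tables, truth = g$truth, planted = planted,
       exclusion_list = planted[1:7], config = cfg)
}
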