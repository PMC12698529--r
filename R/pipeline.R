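#' Run the full pharmacovigilance pipeline from a configuration
#'
#' Orchestrates ingest, de-duplication, case assembly, SMQ case definition,
#' four-method disproportionality with the joint positivity rule,
#' indicated-drug exclusion, IC025 risk tiers, demographic stratification,
#' time-to-onset summaries and the label cross-check, writing tidy CSV
#' outputs and a JSON run manifest whose stage counts record the case
#' funnel.
#'
#' @param config a named list, or the path to a YAML file, with fields:
#'   `tables` (named list/paths of DEMO/DRUG/REAC/THER/OUTC files, or a
#'   directory containing `DEMO.txt` etc.), `smq` (CSV path; default the
#'   packaged hair-loss list), optional `exclusion` (CSV with `drug_name`),
#'   `categories` (CSV with `drug_name`, `category`), `labels` (CSV with
#'   `drug_name`, `documented`), `synonyms` (CSV with `reported_name`,
#'   `normalized_name`), `thresholds` (named overrides for
#'   [signal_thresholds()]), `min_cases`, `stratify` (subset of
#'   c("sex","age")), `out_dir`.
#' @return the manifest, invisibly; outputs are written under `out_dir`.
#' @export
run_full <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    if (!file.exists(config)) stop("config file not found: ", config)
    config <- yaml::read_yaml(config)
  }
  stopifnot(is.list(config))
  out_dir <- config$out_dir %||% "pvsignal_output"

  # validate all referenced files before any compute
  tabs <- config$tables
  if (is.character(tabs) && length(tabs) == 1L && dir.exists(tabs)) {
    tabs <- as.list(file.path(tabs, paste0(
      c("DEMO", "DRUG", "REAC", "THER", "OUTC"), ".txt")))
    names(tabs) <- c("DEMO", "DRUG", "REAC", "THER", "OUTC")
  }
  need <- c("DEMO", "DRUG", "REAC")
  if (!all(need %in% names(tabs))) {
    stop("config$tables must provide at least DEMO, DRUG and REAC")
  }
  files <- c(unlist(tabs), config$smq, config$exclusion, config$categories,
             config$labels, config$synonyms)
  missing <- files[!vapply(files, file.exists, logical(1))]
  if (length(missing)) {
    stop("input file(s) not found: ", paste(missing, collapse = ", "))
  }

  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(config = config, stages = list())

  raw <- lapply(names(tabs), function(nm) read_faers_table(tabs[[nm]], nm))
  names(raw) <- names(tabs)
  manifest$stages$raw_demo_rows <- nrow(raw$DEMO$rows)
  manifest$stages$skipped_rows <- sum(vapply(raw, `[[`, integer(1),
                                             "skipped"))

  demo <- deduplicate(raw$DEMO)
  manifest$stages$deduplicated_cases <- nrow(demo$rows)

  synonyms <- if (!is.null(config$synonyms)) {
    utils::read.csv(config$synonyms, stringsAsFactors = FALSE)
  }
  case_set <- assemble_cases(demo, raw$DRUG, raw$REAC, raw$THER, raw$OUTC,
                             synonyms = synonyms)
  manifest$stages$assembled_cases <- nrow(case_set$cases)
  manifest$stages$assembly_log <- case_set$log

  smq <- if (!is.null(config$smq)) read_smq_csv(config$smq) else alopecia_smq()
  event_ids <- flag_event_cases(case_set, smq)
  manifest$stages$event_cases <- length(event_ids)

  index <- build_drug_case_index(case_set, event_ids)
  manifest$stages$drugs_indexed <- length(index_drugs(index))

  th <- do.call(signal_thresholds, config$thresholds %||% list())
  signals <- signal_table(index, thresholds = th,
                          min_cases = config$min_cases %||% 1L)
  manifest$stages$drugs_tested <- nrow(signals)
  manifest$stages$positive_signals <- sum(signals$positive)

  if (!is.null(config$exclusion)) {
    excl <- utils::read.csv(config$exclusion, stringsAsFactors = FALSE)
    keep <- !signals$drug_name %in% normalize_drug_name(excl$drug_name)
    signals <- signals[keep, , drop = FALSE]
  }
  manifest$stages$positive_after_exclusion <- sum(signals$positive)

  if (!is.null(config$categories)) {
    cats <- utils::read.csv(config$categories, stringsAsFactors = FALSE)
    signals$category <- cats$category[
      match(signals$drug_name, normalize_drug_name(cats$drug_name))]
  }
  tier <- classify_risk_tier(signals$ic025[signals$positive])
  tiers <- data.frame(drug_name = signals$drug_name[signals$positive],
                      ic025 = signals$ic025[signals$positive],
                      tier = tier$tier)
  utils::write.csv(signals, file.path(out_dir, "signals.csv"),
                   row.names = FALSE)
  utils::write.csv(tiers, file.path(out_dir, "risk_tiers.csv"),
                   row.names = FALSE)

  base <- baseline_summary(case_set, event_ids)
  utils::write.csv(base$categorical,
                   file.path(out_dir, "baseline_categorical.csv"),
                   row.names = FALSE)
  utils::write.csv(base$continuous,
                   file.path(out_dir, "baseline_continuous.csv"),
                   row.names = FALSE)

  for (by in config$stratify %||% character(0)) {
    st <- stratified_signals(case_set, event_ids, by = by, thresholds = th)
    utils::write.csv(st, file.path(out_dir,
                                   paste0("signals_by_", by, ".csv")),
                     row.names = FALSE)
  }

  tto <- tto_by_drug(case_set, event_ids)
  utils::write.csv(tto, file.path(out_dir, "tto_by_drug.csv"),
                   row.names = FALSE)
  manifest$stages$tto_drugs <- nrow(tto)

  if (!is.null(config$labels)) {
    ann <- utils::read.csv(config$labels, stringsAsFactors = FALSE)
    lc <- label_crosscheck(signals$drug_name[signals$positive], ann)
    utils::write.csv(lc, file.path(out_dir, "label_crosscheck.csv"),
                     row.names = FALSE)
  }

  manifest$input_md5 <- vapply(unlist(tabs), function(f) {
    unname(tools::md5sum(f))
  }, character(1))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       force = TRUE)
  invisible(manifest)
}
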