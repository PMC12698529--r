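#' Construct an SMQ preferred-term list
#'
#' An SMQ (Standardized MedDRA Query) is a curated set of MedDRA preferred
#' terms defining a clinical condition. Matching is by exact PT string,
#' case-insensitive — MedDRA PTs are a controlled vocabulary, so substring
#' matching would over-match.
#'
#' @param name query name.
#' @param pts character vector of preferred terms (duplicates collapse on
#'   the case-insensitive key).
#' @param scope `"narrow"` or `"broad"`.
#' @return an `smq_term_list`.
#' @export
smq_term_list <- function(name, pts, scope = c("narrow", "broad")) {
  scope <- match.arg(scope)
  pts <- trimws(as.character(pts))
  pts <- pts[nzchar(pts)]
  if (length(pts) == 0L) stop("SMQ term list must contain at least one PT")
  pts <- pts[!duplicated(tolower(pts))]
  structure(list(name = name, scope = scope, pts = pts),
            class = "smq_term_list")
}

#' @export
print.smq_term_list <- function(x, ...) {
  cat(sprintf("<smq_term_list> %s (%s scope): %d PTs\n",
              x$name, x$scope, length(x$pts)))
  invisible(x)
}

#' Read an SMQ term list from CSV
#'
#' @param path CSV with columns `pt` and optionally `scope` (single value).
#' @param name query name (defaults to the file stem).
#' @return an `smq_term_list`.
#' @export
read_smq_csv <- function(path, name = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  stopifnot("pt" %in% names(df))
  scope <- if ("scope" %in% names(df)) unique(tolower(df$scope))[1] else "narrow"
  smq_term_list(name %||% sub("\\.[^.]*$", "", basename(path)),
                df$pt, scope = scope)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' The packaged hair-loss PT list
#'
#' A starter narrow-scope term list for drug-induced alopecia, seeded with
#' the preferred terms commonly analysed at PT level in hair-loss
#' pharmacovigilance work. MedDRA itself is licensed and cannot be
#' redistributed: for real analyses substitute the licensed alopecia SMQ
#' (narrow scope) via [read_smq_csv()].
#'
#' @return an `smq_term_list`.
#' @export
alopecia_smq <- function() {
  read_smq_csv(system.file("extdata", "alopecia_smq_narrow.csv",
                           package = "pvsignal"),
               name = "Alopecia (narrow)")
}

#' Flag target-event cases by SMQ membership
#'
#' A case is flagged iff any of its reaction PTs matches a term of the SMQ
#' (case-insensitive exact match).
#'
#' @param case_set a `faers_case_set`.
#' @param smq an `smq_term_list`.
#' @return character vector of flagged primaryids.
#' @export
flag_event_cases <- function(case_set, smq) {
  stopifnot(inherits(case_set, "faers_case_set"),
            inherits(smq, "smq_term_list"))
  key <- tolower(smq$pts)
  hit <- tolower(case_set$reactions$pt) %in% key
  sort(unique(case_set$reactions$primaryid[hit]))
}

#' Build the per-drug case index
#'
#' Indexes, for every drug, the set of de-duplicated cases in which it
#' appears with a role in `role_filter` (default Primary Suspect only:
#' Secondary Suspect, Concomitant and Interacting entries are excluded to
#' prioritize signal specificity under polypharmacy). Each case contributes
#' at most once per drug and no weighting is applied for co-reported drugs.
#'
#' @param case_set a `faers_case_set`.
#' @param event_ids primaryids of target-event cases
#'   (from [flag_event_cases()]).
#' @param role_filter subset of `c("PS","SS","C","I")`.
#' @return a `drug_case_index`: list with `pairs` (data.table drug_name x
#'   primaryid), `event_cases`, `all_cases`.
#' @export
build_drug_case_index <- function(case_set, event_ids,
                                  role_filter = "PS") {
  stopifnot(inherits(case_set, "faers_case_set"),
            all(role_filter %in% c("PS", "SS", "C", "I")))
  all_cases <- unique(case_set$cases$primaryid)
  event_ids <- intersect(unique(event_ids), all_cases)
  pairs <- unique(case_set$drugs[role %in% role_filter,
                                 .(drug_name, primaryid)])
  structure(list(pairs = pairs,
                 event_cases = event_ids,
                 all_cases = all_cases,
                 role_filter = role_filter),
            class = "drug_case_index")
}

#' @export
print.drug_case_index <- function(x, ...) {
  cat(sprintf(paste0("<drug_case_index> %d drugs (%s), %d event cases of ",
                     "%d total\n"),
              data.table::uniqueN(x$pairs$drug_name),
              paste(x$role_filter, collapse = "/"),
              length(x$event_cases), length(x$all_cases)))
  invisible(x)
}

#' Drugs present in an index
#' @param index a `drug_case_index`.
#' @return sorted character vector of indexed drug names.
#' @export
index_drugs <- function(index) sort(unique(index$pairs$drug_name))

#' Remove drugs indicated for the target condition from the index
#'
#' Drugs approved or guideline-recommended to treat the condition under
#' study are removed before signal interpretation: their disproportionality
#' can be confounded by treatment-failure reporting. Event and total case
#' sets are unchanged.
#'
#' @param index a `drug_case_index`.
#' @param exclusion_list character vector of drug names (normalized with
#'   [normalize_drug_name()] before matching).
#' @return the filtered `drug_case_index`.
#' @export
exclude_indicated_drugs <- function(index, exclusion_list) {
  stopifnot(inherits(index, "drug_case_index"))
  if (length(exclusion_list) == 0L) return(index)
  excl <- normalize_drug_name(exclusion_list)
  index$pairs <- index$pairs[!drug_name %in% excl]
  index
}
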