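#' Read one FAERS-style quarterly ASCII table
#'
#' The public quarterly extracts are '$'-delimited text files with a single
#' header line. Quoted fields do not occur in this dialect and are not
#' supported. Rows whose field count differs from the header are skipped and
#' counted rather than aborting the read.
#'
#' @param path path to the table file.
#' @param table_name one of `"DEMO"`, `"DRUG"`, `"REAC"`, `"THER"`, `"OUTC"`.
#' @return a `raw_record_set`: list with `table_name`, `rows` (a data.table
#'   with lower-cased column names, empty fields as `NA`) and `skipped`
#'   (number of malformed rows dropped).
#' @export
read_faers_table <- function(path, table_name) {
  table_name <- match.arg(toupper(table_name),
                          c("DEMO", "DRUG", "REAC", "THER", "OUTC"))
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  if (length(lines) == 0L || !nzchar(trimws(lines[1L]))) {
    stop("malformed header in ", path, ": empty first line")
  }
  header <- tolower(trimws(strsplit(lines[1L], "$", fixed = TRUE)[[1L]]))
  if (anyDuplicated(header) || any(!nzchar(header))) {
    stop("malformed header in ", path,
         ": duplicate or empty column names")
  }
  k <- length(header)
  body <- lines[-1L]
  body <- body[nzchar(body)]
  # sentinel keeps trailing empty fields, which strsplit would drop
  parts <- strsplit(paste0(body, "\x01"), "$", fixed = TRUE)
  parts <- lapply(parts, function(p) {
    p[length(p)] <- sub("\x01$", "", p[length(p)])
    p
  })
  nf <- lengths(parts)
  bad <- nf != k
  skipped <- sum(bad)
  parts <- parts[!bad]
  if (length(parts)) {
    mat <- matrix(unlist(parts, use.names = FALSE), ncol = k, byrow = TRUE)
    mat[!nzchar(trimws(mat))] <- NA_character_
    rows <- data.table::as.data.table(mat)
    data.table::setnames(rows, header)
  } else {
    rows <- data.table::setnames(
      data.table::as.data.table(matrix(character(0), ncol = k)), header)
  }
  new_raw_record_set(table_name, rows, skipped)
}

#' Construct a raw record set from an in-memory table
#'
#' @param table_name table id (DEMO/DRUG/REAC/THER/OUTC).
#' @param rows data.frame of raw fields (coerced to character data.table,
#'   names lower-cased).
#' @param skipped malformed-row counter carried from parsing.
#' @return a `raw_record_set`.
#' @export
new_raw_record_set <- function(table_name, rows, skipped = 0L) {
  rows <- data.table::as.data.table(rows)
  if (ncol(rows)) {
    rows <- rows[, lapply(.SD, as.character)]
    data.table::setnames(rows, tolower(names(rows)))
  }
  structure(list(table_name = table_name, rows = rows,
                 skipped = as.integer(skipped)),
            class = "raw_record_set")
}

#' @export
print.raw_record_set <- function(x, ...) {
  cat(sprintf("<raw_record_set> %s: %d rows (%d skipped)\n",
              x$table_name, nrow(x$rows), x$skipped))
  invisible(x)
}

#' De-duplicate DEMO records per the FDA-recommended rule
#'
#' Spontaneous reports arrive in multiple versions sharing a CASEID. For each
#' CASEID the version with the most recent FDA receipt date (FDA_DT) is
#' retained; among equal dates the highest PRIMARYID wins. Records with an
#' unparseable FDA_DT rank below any dated version. Output rows are sorted by
#' caseid, so the operation is deterministic and idempotent.
#'
#' @param demo a `raw_record_set` for the DEMO table; rows must carry
#'   `primaryid`, `caseid` and `fda_dt`.
#' @return a `raw_record_set` with exactly one row per caseid; the number of
#'   rows removed is attached as attribute `n_removed`.
#' @export
deduplicate <- function(demo) {
  stopifnot(inherits(demo, "raw_record_set"))
  rows <- data.table::copy(demo$rows)
  need <- c("primaryid", "caseid", "fda_dt")
  if (!all(need %in% names(rows))) {
    stop("DEMO rows must carry columns: ", paste(need, collapse = ", "))
  }
  if (nrow(rows) == 0L) return(demo)
  ord <- parse_partial_date(rows$fda_dt)$ord
  ord[is.na(ord)] <- -Inf  # undated versions never beat dated ones
  pid <- suppressWarnings(as.numeric(rows$primaryid))
  if (anyNA(pid)) pid <- xtfrm(rows$primaryid)  # non-numeric ids: string order
  o <- order(rows$caseid, ord, pid)
  rows <- rows[o]
  keep <- !duplicated(rows$caseid, fromLast = TRUE)
  out <- rows[keep]
  out <- out[order(out$caseid)]
  res <- new_raw_record_set(demo$table_name, out, demo$skipped)
  attr(res, "n_removed") <- nrow(rows) - nrow(out)
  res
}

# age in years from FAERS AGE / AGE_COD
.age_to_years <- function(age, age_cod) {
  v <- suppressWarnings(as.numeric(age))
  cod <- toupper(trimws(ifelse(is.na(age_cod), "YR", age_cod)))
  f <- c(DEC = 10, YR = 1, MON = 1 / 12, WK = 1 / 52, DY = 1 / 365.25)
  mult <- unname(f[cod])
  out <- v * mult
  out[is.na(mult)] <- NA_real_
  out[!is.na(out) & (out < 0 | out > 130)] <- NA_real_
  out
}

# weight in kg from FAERS WT / WT_COD
.wt_to_kg <- function(wt, wt_cod) {
  v <- suppressWarnings(as.numeric(wt))
  cod <- toupper(trimws(ifelse(is.na(wt_cod), "KG", wt_cod)))
  out <- ifelse(cod == "LBS", v * 0.4536, v)
  out[!(cod %in% c("KG", "LBS"))] <- NA_real_
  out[!is.na(out) & (out <= 0 | out >= 700)] <- NA_real_
  out
}

.col_or_na <- function(dt, col) {
  if (col %in% names(dt)) dt[[col]] else rep(NA_character_, nrow(dt))
}

#' Assemble de-duplicated case-level records from the five FAERS tables
#'
#' Joins DRUG, REAC, THER and OUTC rows onto the (already de-duplicated)
#' DEMO table by primaryid. Ages are converted to years (DEC x10, YR x1,
#' MON /12, WK /52, DY /365.25), weights to kg (LBS x0.4536); values outside
#' plausibility bounds (age 0-130 y, weight 0-700 kg) become missing. Drug
#' names are normalized (upper case, collapsed whitespace, optional synonym
#' mapping); a drug repeated within one case with the same name and role
#' collapses to a single entry keeping the earliest start date. A case is
#' "serious" iff it carries at least one outcome code.
#'
#' @param demo,drug,reac,ther,outc `raw_record_set`s; `demo` must already be
#'   de-duplicated.
#' @param synonyms optional synonym data.frame passed to
#'   [normalize_drug_name()].
#' @return a `faers_case_set`: list of data.tables `cases` (one row per
#'   primaryid with demographics), `drugs` (primaryid, drug_name, role,
#'   route, start date/precision), `reactions` (primaryid, pt) and
#'   `outcomes` (primaryid, outc_cod), plus a `log` of drop counters.
#' @export
assemble_cases <- function(demo, drug, reac, ther = NULL, outc = NULL,
                           synonyms = NULL) {
  d <- demo$rows
  stopifnot(nrow(d) > 0L, !anyDuplicated(d$caseid))
  log <- list()

  fda <- parse_partial_date(.col_or_na(d, "fda_dt"))
  evt <- parse_partial_date(.col_or_na(d, "event_dt"))
  sex_raw <- toupper(trimws(.col_or_na(d, "sex")))
  sex <- ifelse(sex_raw %in% c("F", "M"), sex_raw, "unknown")
  cases <- data.table::data.table(
    primaryid = d$primaryid,
    caseid = .col_or_na(d, "caseid"),
    fda_dt = fda$date, fda_precision = fda$precision, fda_ord = fda$ord,
    event_dt = evt$date, event_precision = evt$precision,
    age_years = .age_to_years(.col_or_na(d, "age"), .col_or_na(d, "age_cod")),
    sex = sex,
    weight_kg = .wt_to_kg(.col_or_na(d, "wt"), .col_or_na(d, "wt_cod")),
    reporter_occupation = .col_or_na(d, "occp_cod"),
    country = .col_or_na(d, "reporter_country")
  )
  keep_ids <- cases$primaryid

  # outcomes ------------------------------------------------------------
  if (!is.null(outc) && nrow(outc$rows)) {
    ot <- outc$rows[, .(primaryid, outc_cod = toupper(trimws(outc_cod)))]
    log$outc_orphans <- sum(!ot$primaryid %in% keep_ids)
    ot <- unique(ot[ot$primaryid %in% keep_ids])
  } else {
    ot <- data.table::data.table(primaryid = character(0),
                                 outc_cod = character(0))
  }
  cases[, serious := primaryid %in% ot$primaryid]

  # drugs ---------------------------------------------------------------
  dr <- drug$rows
  log$drug_orphans <- sum(!dr$primaryid %in% keep_ids)
  dr <- dr[dr$primaryid %in% keep_ids]
  role <- toupper(trimws(.col_or_na(dr, "role_cod")))
  ok_role <- role %in% c("PS", "SS", "C", "I")
  log$drug_bad_role <- sum(!ok_role)
  dr <- dr[ok_role]
  role <- role[ok_role]
  dtab <- data.table::data.table(
    primaryid = dr$primaryid,
    drug_seq = .col_or_na(dr, "drug_seq"),
    drug_name = normalize_drug_name(.col_or_na(dr, "drugname"), synonyms),
    role = role,
    route = .col_or_na(dr, "route")
  )
  dtab <- dtab[nzchar(drug_name) & !is.na(drug_name)]
  # therapy start dates join on (primaryid, drug_seq)
  if (!is.null(ther) && nrow(ther$rows)) {
    th <- ther$rows
    sd <- parse_partial_date(.col_or_na(th, "start_dt"))
    th2 <- data.table::data.table(primaryid = th$primaryid,
                                  drug_seq = .col_or_na(th, "dsg_drug_seq"),
                                  start_dt = sd$date,
                                  start_precision = sd$precision,
                                  start_ord = sd$ord)
    dtab <- merge(dtab, th2, by = c("primaryid", "drug_seq"),
                  all.x = TRUE, sort = FALSE)
  } else {
    dtab[, `:=`(start_dt = as.Date(NA), start_precision = "none",
                start_ord = NA_real_)]
  }
  # collapse repeats of the same drug+role within a case: earliest start
  data.table::setorderv(dtab, c("primaryid", "drug_name", "role", "start_ord"),
                        na.last = TRUE)
  before <- nrow(dtab)
  dtab <- dtab[!duplicated(dtab[, .(primaryid, drug_name, role)])]
  log$drug_collapsed <- before - nrow(dtab)
  dtab[, drug_seq := NULL]

  # reactions -----------------------------------------------------------
  rc <- reac$rows
  log$reac_orphans <- sum(!rc$primaryid %in% keep_ids)
  rc <- rc[rc$primaryid %in% keep_ids]
  rtab <- unique(data.table::data.table(primaryid = rc$primaryid,
                                        pt = trimws(.col_or_na(rc, "pt"))))
  rtab <- rtab[nzchar(pt) & !is.na(pt)]

  # enforce non-empty drugs and reactions per retained case
  has_drug <- cases$primaryid %in% dtab$primaryid
  has_pt <- cases$primaryid %in% rtab$primaryid
  log$cases_dropped_incomplete <- sum(!(has_drug & has_pt))
  cases <- cases[has_drug & has_pt]
  dtab <- dtab[primaryid %in% cases$primaryid]
  rtab <- rtab[primaryid %in% cases$primaryid]
  ot <- ot[primaryid %in% cases$primaryid]

  structure(list(cases = cases, drugs = dtab, reactions = rtab,
                 outcomes = ot, log = log),
            class = "faers_case_set")
}

#' @export
print.faers_case_set <- function(x, ...) {
  cat(sprintf(paste0("<faers_case_set> %d cases, %d drug entries, ",
                     "%d reaction PTs\n"),
              nrow(x$cases), nrow(x$drugs), nrow(x$reactions)))
  invisible(x)
}

#' Write raw record sets as FAERS-style '$'-delimited files
#'
#' @param tables named list of `raw_record_set`s (names used as file stems).
#' @param dir output directory (created if absent).
#' @return invisibly, the written file paths.
#' @export
write_faers_tables <- function(tables, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  for (nm in names(tables)) {
    rrs <- tables[[nm]]
    stopifnot(inherits(rrs, "raw_record_set"))
    path <- file.path(dir, paste0(nm, ".txt"))
    rows <- rrs$rows[, lapply(.SD, function(x) {
      x <- as.character(x); x[is.na(x)] <- ""; x
    })]
    lines <- c(paste(names(rows), collapse = "$"),
               do.call(paste, c(as.list(rows), sep = "$")))
    writeLines(lines, path)
    paths <- c(paths, path)
  }
  invisible(paths)
}
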