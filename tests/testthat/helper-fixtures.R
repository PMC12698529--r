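# in-code fixtures shared across test files

write_lines_tmp <- function(lines) {
  path <- tempfile(fileext = ".txt")
  writeLines(lines, path)
  path
}

# a hand-checkable five-table bundle: 4 cases (one duplicated), drug roles
# PS/SS/C, alopecia PTs on cases 101/103
tiny_tables <- function() {
  demo <- new_raw_record_set("DEMO", data.frame(
    primaryid = c("1012", "1011", "1021", "1031", "1041"),
    caseid    = c("101",  "101",  "102",  "103",  "104"),
    fda_dt    = c("20230301", "20230101", "20220515", "20210707", "20200101"),
    event_dt  = c("20230110", "20230110", "20220401", "202106", ""),
    age       = c("600", "600", "45", "", "70"),
    age_cod   = c("MON", "MON", "YR", "", "YR"),
    sex       = c("F", "F", "M", "F", ""),
    wt        = c("154", "154", "80", "", ""),
    wt_cod    = c("LBS", "LBS", "KG", "", ""),
    occp_cod  = c("CN", "CN", "MD", "CN", ""),
    reporter_country = c("US", "US", "CA", "US", "GB")))
  drug <- new_raw_record_set("DRUG", data.frame(
    primaryid = c("1012", "1012", "1012", "1021", "1031", "1041"),
    drug_seq  = c("1", "2", "3", "1", "1", "1"),
    role_cod  = c("PS", "PS", "C", "PS", "SS", "PS"),
    drugname  = c("drug x", "DRUG  X", "DRUG Y", "DRUG Y", "DRUG X",
                  "DRUG Z"),
    route     = c("ORAL", "ORAL", "", "ORAL", "", "ORAL")))
  reac <- new_raw_record_set("REAC", data.frame(
    primaryid = c("1012", "1012", "1021", "1031", "1041"),
    pt = c("Alopecia", "Nausea", "Headache", "ALOPECIA AREATA", "Rash")))
  ther <- new_raw_record_set("THER", data.frame(
    primaryid = c("1012", "1012", "1021", "1041"),
    dsg_drug_seq = c("1", "2", "1", "1"),
    start_dt = c("20230105", "20221201", "20220301", "20190101")))
  outc <- new_raw_record_set("OUTC", data.frame(
    primaryid = c("1012", "1031"),
    outc_cod = c("HO", "OT")))
  list(DEMO = demo, DRUG = drug, REAC = reac, THER = ther, OUTC = outc)
}

tiny_case_set <- function() {
  tt <- tiny_tables()
  assemble_cases(deduplicate(tt$DEMO), tt$DRUG, tt$REAC, tt$THER, tt$OUTC)
}

# independent closed-form re-evaluations used as oracles
oracle_ror <- function(a, b, c, d, z = 1.96) {
  or <- (a / b) / (c / d)
  half <- z * sqrt(1 / a + 1 / b + 1 / c + 1 / d)
  c(or, or * exp(-half), or * exp(half))
}

oracle_prr_chi2 <- function(a, b, c, d) {
  n <- a + b + c + d
  prr <- (a * (c + d)) / (c * (a + b))
  exp_cells <- outer(c(a + b, c + d), c(a + c, b + d)) / n
  obs <- matrix(c(a, b, c, d), 2, byrow = TRUE)
  c(prr, sum((obs - exp_cells)^2 / exp_cells))
}

oracle_ic <- function(a, b, c, d) {
  e <- (a + b) / (a + b + c + d) * (a + c)
  ic <- (log((a + 0.5) / (e + 0.5))) / log(2)
  c(ic, ic - 3.3 / sqrt(a + 0.5) - 2 / (a + 0.5)^1.5)
}

# two-sided Fisher p by full hypergeometric enumeration over the support
oracle_fisher_p <- function(a, b, c, d) {
  m <- a + b; n <- c + d; k <- a + c
  support <- max(0, k - n):min(k, m)
  pr <- dhyper(support, m, n, k)
  sum(pr[pr <= pr[support == a] * (1 + 1e-7)])
}

# two-sided exact rank-sum p by enumeration of all group assignments
oracle_wilcoxon_p <- function(x, y) {
  pooled <- c(x, y)
  stopifnot(!anyDuplicated(pooled))
  r <- rank(pooled)
  n1 <- length(x)
  w_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  ws <- combn(length(pooled), n1,
              function(i) sum(r[i]) - n1 * (n1 + 1) / 2)
  min(1, 2 * min(mean(ws <= w_obs), mean(ws >= w_obs)))
}
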