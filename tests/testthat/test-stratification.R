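test_that("age bands split at 18/45/65 with >=65 closed", {
  expect_equal(age_band(c(0, 17.9, 18, 44, 45, 64.9, 65, 90, NA)),
               c("<18", "<18", "18-44", "18-44", "45-64", "45-64",
                 ">=65", ">=65", NA))
})

test_that("baseline percentages are half-up shares of the event total", {
  g <- generate_reports(synthetic_config(n_cases = 3000, n_drugs = 10,
                                         event_base_rate = 0.2, seed = 14))
  res <- suppressWarnings(run_signal_pipeline(g$tables, fisher = FALSE))
  b <- baseline_summary(res$case_set, res$event_ids)
  expect_equal(b$n_total, length(res$event_ids))
  sex <- b$categorical[b$categorical$block == "sex", ]
  expect_equal(sum(sex$n), b$n_total)
  # exhaustive blocks sum to 100% up to rounding
  expect_lt(abs(sum(sex$pct) - 100), 0.05)
  yr <- b$categorical[b$categorical$block == "reporting_year", ]
  expect_lt(abs(sum(yr$pct) - 100), 0.05)
  expect_equal(sex$pct, share_pct(sex$n, b$n_total))
})

test_that("an all-unknown-sex panel reports unknown 100.00", {
  demo <- new_raw_record_set("DEMO", data.frame(
    primaryid = as.character(1:5), caseid = as.character(1:5),
    fda_dt = "20230101", sex = ""))
  drug <- new_raw_record_set("DRUG", data.frame(
    primaryid = as.character(1:5), drug_seq = "1", role_cod = "PS",
    drugname = "A"))
  reac <- new_raw_record_set("REAC", data.frame(
    primaryid = as.character(1:5), pt = "Alopecia"))
  b <- baseline_summary(assemble_cases(demo, drug, reac))
  sex <- b$categorical[b$categorical$block == "sex", ]
  expect_equal(sex$level, "unknown")
  expect_equal(sex$pct, 100)
})

test_that("risk tiers follow the IC025 boundaries", {
  r <- classify_risk_tier(c(5.61, 2.87, 1.5, 3, 3.0001, 0.2, NA))
  expect_equal(r$tier,
               c("high", "medium", "low", "medium", "high", "low", NA))
  expect_equal(unname(r$counts), c(2, 2, 2))
  expect_equal(sum(r$counts), 6)  # NA left unclassified
})

test_that("a planted male-only effect surfaces only in the male stratum", {
  cfg <- synthetic_config(n_cases = 30000, n_drugs = 20,
                          event_base_rate = 0.01,
                          female_share = 0.5, male_share = 0.45,
                          missing_age_rate = 0.2, seed = 88)
  g <- generate_reports(cfg)
  cs <- assemble_cases(deduplicate(g$tables$DEMO), g$tables$DRUG,
                       g$tables$REAC, g$tables$THER, g$tables$OUTC)
  # plant the effect post hoc: males on DRUG 007 get the event added
  males <- cs$cases$primaryid[cs$cases$sex == "M"]
  target <- cs$drugs[cs$drugs$drug_name == "DRUG 007" &
                     cs$drugs$role == "PS" &
                     cs$drugs$primaryid %in% males, ]
  add <- target$primaryid[seq_len(floor(nrow(target) * 0.12))]
  cs$reactions <- rbind(cs$reactions,
                        data.table::data.table(primaryid = add,
                                               pt = "Alopecia"))
  ev <- flag_event_cases(cs, alopecia_smq())
  st <- suppressWarnings(stratified_signals(cs, ev, by = "sex"))
  m <- st[st$stratum == "M" & st$drug_name == "DRUG 007", ]
  f <- st[st$stratum == "F" & st$drug_name == "DRUG 007", ]
  expect_true(m$positive)
  expect_true(nrow(f) == 0 || !f$positive)
})

test_that("a whole-population stratum reproduces the unstratified table", {
  g <- generate_reports(synthetic_config(n_cases = 4000, n_drugs = 10,
                                         event_base_rate = 0.1,
                                         female_share = 1, male_share = 0,
                                         seed = 19))
  res <- suppressWarnings(run_signal_pipeline(g$tables))
  st <- stratified_signals(res$case_set, res$event_ids, by = "sex",
                           min_cases = 1L,
                           prior = attr(res$signals, "prior"))
  expect_equal(unique(st$stratum), "F")
  expect_equal(st[, c("drug_name", "a", "b", "c", "d", "ror", "ic025")],
               res$signals[, c("drug_name", "a", "b", "c", "d", "ror",
                               "ic025")],
               ignore_attr = TRUE)
})

test_that("Bonferroni family size is the per-stratum drug count", {
  g <- generate_reports(synthetic_config(n_cases = 4000, n_drugs = 10,
                                         event_base_rate = 0.1,
                                         female_share = 1, male_share = 0,
                                         seed = 19))
  res <- suppressWarnings(run_signal_pipeline(g$tables))
  st <- suppressWarnings(
    stratified_signals(res$case_set, res$event_ids, by = "sex",
                       min_cases = 1L))
  expect_equal(st$p_adjusted, pmin(1, nrow(st) * st$fisher_p))
  # arithmetic of the lost-significance rule
  expect_equal(min(1, 10 * 0.01), 0.1)
  expect_true(all(st$lost_significance ==
                    (st$fisher_p < 0.05 & st$p_adjusted >= 0.05)))
})

test_that("PT-level shares are per-PT case fractions", {
  demo <- new_raw_record_set("DEMO", data.frame(
    primaryid = as.character(1:6), caseid = as.character(1:6),
    fda_dt = "20230101"))
  drug <- new_raw_record_set("DRUG", data.frame(
    primaryid = as.character(c(1, 2, 3, 4, 5, 6)),
    drug_seq = "1", role_cod = "PS",
    drugname = c("A", "A", "A", "B", "A", "B")))
  reac <- new_raw_record_set("REAC", data.frame(
    primaryid = as.character(c(1, 2, 3, 4, 5, 6)),
    pt = c("Alopecia", "Alopecia", "Alopecia", "Alopecia",
           "Hypotrichosis", "Hypotrichosis")))
  cs <- assemble_cases(demo, drug, reac)
  d <- pt_level_distribution(cs, alopecia_smq())
  al <- d[d$pt == "Alopecia", ]
  expect_equal(al$share[al$drug_name == "A"], 75)   # 3 of 4
  expect_equal(al$share[al$drug_name == "B"], 25)
  # one-drug PT: 100%
  hy <- d[d$pt == "Hypotrichosis", ]
  expect_true(all(hy$n_pt_cases == 2))
  # shares within a PT from single-PS cases sum to 100
  expect_equal(sum(al$share), 100)
})

test_that("label cross-check partitions and rounds half-up to 1 decimal", {
  drugs <- sprintf("D%02d", 1:64)
  ann <- data.frame(drug_name = drugs,
                    documented = rep(c(TRUE, FALSE), c(49, 15)))
  lc <- label_crosscheck(drugs, ann)
  expect_equal(lc$n[lc$status == "documented"], 49)
  expect_equal(lc$pct[lc$status == "documented"], 76.6)
  expect_equal(lc$pct[lc$status == "undocumented"], 23.4)
  # zero documented
  lc0 <- label_crosscheck(drugs[1:5],
                          data.frame(drug_name = drugs[1:5],
                                     documented = FALSE))
  expect_equal(lc0$pct[lc0$status == "documented"], 0)
  # missing annotations become unknown
  lc1 <- label_crosscheck(c("D01", "ZZZ"),
                          data.frame(drug_name = "D01", documented = TRUE))
  expect_equal(lc1$n[lc1$status == "unknown"], 1)
})
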