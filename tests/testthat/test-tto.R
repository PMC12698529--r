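make_tto_case_set <- function(starts, events, drug = "A") {
  n <- length(starts)
  demo <- new_raw_record_set("DEMO", data.frame(
    primaryid = as.character(1:n), caseid = as.character(1:n),
    fda_dt = "20230601", event_dt = events))
  dr <- new_raw_record_set("DRUG", data.frame(
    primaryid = as.character(1:n), drug_seq = "1", role_cod = "PS",
    drugname = drug))
  reac <- new_raw_record_set("REAC", data.frame(
    primaryid = as.character(1:n), pt = "Alopecia"))
  ther <- new_raw_record_set("THER", data.frame(
    primaryid = as.character(1:n), dsg_drug_seq = "1", start_dt = starts))
  assemble_cases(demo, dr, reac, ther)
}

test_that("extract_tto keeps only usable day-precision, non-negative pairs", {
  cs <- make_tto_case_set(
    starts = c("20230101", "20230201", "202301", "", "20230301"),
    events = c("20230131", "20230115", "20230120", "20230401", "2023"))
  rec <- extract_tto(cs, "A")
  # case 1: 30 days; case 2: event before start; case 3: month-precision
  # start; case 4: missing start; case 5: year-precision event
  expect_equal(rec$days, 30L)
  ex <- attr(rec, "exclusions")
  expect_equal(unname(ex["negative_days"]), 1L)
  expect_equal(unname(ex["no_event_date"]), 1L)
})

test_that("extract_tto uses the earliest PS start and ignores case order", {
  demo <- new_raw_record_set("DEMO", data.frame(
    primaryid = "1", caseid = "1", fda_dt = "20230601",
    event_dt = "20230301"))
  dr <- new_raw_record_set("DRUG", data.frame(
    primaryid = "1", drug_seq = c("1", "2"), role_cod = c("PS", "PS"),
    drugname = c("A", "a")))
  reac <- new_raw_record_set("REAC", data.frame(primaryid = "1",
                                                pt = "Alopecia"))
  ther <- new_raw_record_set("THER", data.frame(
    primaryid = "1", dsg_drug_seq = c("1", "2"),
    start_dt = c("20230201", "20230101")))
  cs <- assemble_cases(demo, dr, reac, ther)
  expect_equal(extract_tto(cs, "A")$days, 59L)

  g <- generate_reports(synthetic_config(n_cases = 500, n_drugs = 4,
                                         event_base_rate = 0.5, seed = 3))
  cs2 <- assemble_cases(deduplicate(g$tables$DEMO), g$tables$DRUG,
                        g$tables$REAC, g$tables$THER, g$tables$OUTC)
  r1 <- extract_tto(cs2)
  cs3 <- cs2
  perm <- sample(nrow(cs3$drugs))
  cs3$drugs <- cs3$drugs[perm]
  r2 <- extract_tto(cs3)
  expect_equal(r1, r2, ignore_attr = TRUE)
})

test_that("summaries use median-of-halves quartiles and half-open bins", {
  s <- summarize_tto(c(0, 10, 20))
  expect_equal(s$median, 10)
  s1 <- summarize_tto(31)
  expect_equal(c(s1$q1, s1$median, s1$q3), c(31, 31, 31))
  set.seed(10)
  x <- round(rweibull(100, 1.3, 90))
  s2 <- summarize_tto(x)
  fn <- fivenum(sort(x))  # sort-based Tukey-hinge oracle
  expect_equal(c(s2$q1, s2$median, s2$q3), fn[2:4])
  expect_equal(sum(s2$histogram$n), 100)
  expect_lt(abs(sum(s2$histogram$pct) - 100), 0.1)
  # 29 is in [0,30) but 30 is not
  h <- summarize_tto(c(29, 30))$histogram
  expect_equal(h$n[h$bin == "[0,30)"], 1)
  expect_equal(h$n[h$bin == "[30,60)"], 1)
})

test_that("Weibull fitting recovers known parameters", {
  set.seed(5)
  x <- rweibull(5000, 1, 100)   # exponential special case
  f <- fit_weibull(x)
  expect_gt(f$shape, 0.95); expect_lt(f$shape, 1.05)
  expect_equal(f$median_days, 100 * log(2), tolerance = 0.05)
  expect_true(f$ci_shape[1] < f$shape && f$shape < f$ci_shape[2])
  expect_true(f$ci_scale[1] < f$scale && f$scale < f$ci_scale[2])
  # closed-form median consistency against simulation
  set.seed(6)
  draws <- rweibull(1e5, 2, 120)
  expect_equal(median(draws), 120 * log(2)^(1 / 2), tolerance = 0.02)
  # preconditions
  expect_error(fit_weibull(c(3, 5, 9)), "at least 10")
  expect_error(fit_weibull(rep(4, 20)), "distinct")
})

test_that("zero-day onsets are kept in summaries but shifted for the fit", {
  x <- c(rep(0, 30), round(rweibull(200, 1.5, 60)))
  s <- summarize_tto(x)
  expect_equal(s$n, 230)
  f <- fit_weibull(x)
  expect_true(is.finite(f$shape) && f$shape > 0)
})

test_that("rank-sum comparisons match exact enumeration on small groups", {
  ident <- compare_tto_groups(c(1, 2, 3), c(1, 2, 3))
  expect_equal(ident$p_value, 1)
  sep <- compare_tto_groups(c(1, 2, 3), c(10, 11, 12))
  expect_equal(sep$p_value, 0.1)
  expect_equal(sep$method, "exact")
  expect_equal(sep$p_value, oracle_wilcoxon_p(c(1, 2, 3), c(10, 11, 12)))
  set.seed(8)
  for (i in 1:10) {
    x <- sample(1:100, 5); y <- setdiff(sample(1:100, 12), x)[1:5]
    got <- compare_tto_groups(x, y)$p_value
    expect_equal(got, oracle_wilcoxon_p(x, y), tolerance = 1e-12)
  }
  # normal approximation agrees with exact within 0.02 at n1 = n2 = 6
  for (i in 1:10) {
    x <- sample(seq(1, 299, 2), 6); y <- sample(seq(2, 300, 2), 6)
    exact_p <- oracle_wilcoxon_p(x, y)
    approx_p <- suppressWarnings(
      stats::wilcox.test(x, y, exact = FALSE, correct = TRUE))$p.value
    expect_lt(abs(exact_p - approx_p), 0.02)
  }
  expect_error(compare_tto_groups(numeric(0), 1:3), "non-empty")
})

test_that("per-drug TTO table mirrors the summary columns", {
  g <- generate_reports(synthetic_config(
    n_cases = 3000, n_drugs = 3, event_base_rate = 0.6,
    tto_params = data.frame(drug_name = "DRUG 001", shape = 2,
                            scale = 120),
    missing_date_rate = 0.05, partial_date_rate = 0.05, seed = 44))
  res <- suppressWarnings(run_signal_pipeline(g$tables, fisher = FALSE))
  tab <- tto_by_drug(res$case_set, res$event_ids)
  expect_true(all(c("drug_name", "n", "median", "q1", "q3", "shape",
                    "scale") %in% names(tab)))
  expect_true(all(tab$q1 <= tab$median & tab$median <= tab$q3))
  d1 <- tab[tab$drug_name == "DRUG 001", ]
  expect_gt(d1$shape, 1.6); expect_lt(d1$shape, 2.4)
})
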