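worked <- contingency(10, 90, 100, 9900)

test_that("ROR, PRR and IC match independent closed-form evaluation", {
  r <- compute_ror(worked)
  o <- oracle_ror(10, 90, 100, 9900)
  expect_equal(c(r$ror, r$ror_lo, r$ror_hi), o, tolerance = 1e-12)
  expect_equal(r$ror, 11)

  p <- compute_prr(worked)
  op <- oracle_prr_chi2(10, 90, 100, 9900)
  expect_equal(c(p$prr, p$chi2), op, tolerance = 1e-12)
  expect_equal(p$prr, 10)

  ic <- compute_ic(worked)
  oi <- oracle_ic(10, 90, 100, 9900)
  expect_equal(c(ic$ic, ic$ic025), oi, tolerance = 1e-12)
  # unshrunk observed/expected variant
  expect_equal(compute_ic(worked, shrunk = FALSE)$ic,
               log2(10 * 10100 / (100 * 110)), tolerance = 1e-12)
})

test_that("homogeneous tables are exactly null", {
  t0 <- contingency(25, 25, 25, 25)
  expect_equal(compute_ror(t0)$ror, 1)
  p <- compute_prr(t0)
  expect_equal(p$prr, 1)
  expect_equal(p$chi2, 0)
  # a/(a+b) == c/(c+d) with unequal margins
  t1 <- contingency(10, 90, 30, 270)
  expect_equal(compute_prr(t1)$prr, 1)
  expect_equal(compute_prr(t1)$chi2, 0)
})

test_that("Yates correction shrinks the chi-square", {
  expect_lt(compute_prr(worked, yates = TRUE)$chi2,
            compute_prr(worked)$chi2)
})

test_that("zero cells yield undefined markers unless corrected", {
  tz <- contingency(0, 100, 100, 9800)
  expect_true(is.na(compute_ror(tz)$ror))
  expect_false(is.na(compute_ror(tz, haldane = TRUE)$ror))
  expect_true(is.na(compute_prr(contingency(5, 5, 0, 90))$prr))
  # IC is shrunk and always defined
  expect_true(is.finite(compute_ic(tz)$ic025))
})

test_that("statistics agree in sign and intervals bracket the estimate", {
  set.seed(101)
  for (i in 1:1000) {
    cells <- rmultinom(1, size = sample(50:5000, 1),
                       prob = c(0.02, 0.18, 0.1, 0.7))[, 1]
    if (any(cells == 0)) next
    t <- contingency(cells[1], cells[2], cells[3], cells[4])
    r <- compute_ror(t); p <- compute_prr(t); ic <- compute_ic(t)
    expect_equal(c(r$ror, r$ror_lo, r$ror_hi),
                 oracle_ror(cells[1], cells[2], cells[3], cells[4]),
                 tolerance = 1e-10)
    expect_equal(c(p$prr, p$chi2),
                 oracle_prr_chi2(cells[1], cells[2], cells[3], cells[4]),
                 tolerance = 1e-10)
    expect_equal(c(ic$ic, ic$ic025),
                 oracle_ic(cells[1], cells[2], cells[3], cells[4]),
                 tolerance = 1e-10)
    # sign agreement: ROR > 1 <=> PRR > 1 <=> ad > bc
    ad_gt <- cells[1] * cells[4] > cells[2] * cells[3]
    expect_equal(r$ror > 1, ad_gt)
    expect_equal(p$prr > 1, ad_gt)
    expect_true(r$ror_lo < r$ror && r$ror < r$ror_hi)
    expect_true(ic$ic025 < ic$ic)
  }
})

test_that("Fisher exact p matches hypergeometric enumeration", {
  expect_equal(fisher_volcano(data.frame(a = 3, b = 1, c = 1, d = 3))$fisher_p,
               34 / 70, tolerance = 1e-12)
  set.seed(33)
  for (i in 1:50) {
    cells <- as.integer(rmultinom(1, sample(8:40, 1), c(1, 1, 1, 1) / 4))
    got <- fisher_volcano(data.frame(a = cells[1], b = cells[2],
                                     c = cells[3], d = cells[4]))$fisher_p
    expect_equal(got, oracle_fisher_p(cells[1], cells[2], cells[3],
                                      cells[4]),
                 tolerance = 1e-9)
  }
})

test_that("Bonferroni adjustment multiplies and clips", {
  fv <- fisher_volcano(data.frame(a = 3, b = 1, c = 1, d = 3), m = 1)
  expect_equal(fv$p_adjusted, fv$fisher_p)   # m = 1 identity
  expect_equal(min(1, 64 * 0.04), 1)         # clipping rule
  fv2 <- fisher_volcano(data.frame(a = c(30, 3), b = c(5, 1),
                                   c = c(5, 1), d = c(30, 3)))
  expect_equal(fv2$p_adjusted, pmin(1, 2 * fv2$fisher_p))
})

test_that("the joint rule needs all four methods and a count floor", {
  th <- signal_thresholds()
  pr <- mgps_prior(0.2, 0.1, 2, 4, 1 / 3)
  eval_one <- function(t) {
    s <- cbind(compute_ror(t), compute_prr(t), compute_ic(t),
               compute_ebgm(t, pr))
    evaluate_signal(t, s, th)
  }
  # a = 2: never positive regardless of magnitudes
  v <- eval_one(contingency(2, 1, 5, 10000))
  expect_false(v$positive)
  expect_false(v$ror_pos); expect_false(v$prr_pos)
  # homogeneous table: all flags false
  v0 <- eval_one(contingency(25, 25, 25, 25))
  expect_false(any(unlist(v0[, c("ror_pos", "prr_pos", "bcpnn_pos",
                                 "mgps_pos")])))
  # strongly disproportionate worked table: positive end to end
  v1 <- eval_one(contingency(50, 450, 100, 49400))
  expect_true(v1$positive)
})

test_that("contingency cells equal a brute-force recount of raw cases", {
  g <- generate_reports(synthetic_config(n_cases = 2000, n_drugs = 8,
                                         event_base_rate = 0.05,
                                         effect_map = c("DRUG 001" = 6),
                                         seed = 12))
  res <- suppressWarnings(run_signal_pipeline(g$tables, fisher = FALSE))
  cs <- res$case_set
  ev <- res$event_ids
  ps <- unique(as.data.frame(cs$drugs[cs$drugs$role == "PS",
                                      c("primaryid", "drug_name")]))
  for (d in index_drugs(res$index)) {
    ids <- ps$primaryid[ps$drug_name == d]
    t <- build_contingency(res$index, d)
    expect_equal(t$a, sum(ids %in% ev))
    expect_equal(t$b, sum(!ids %in% ev))
    expect_equal(t$c, sum(!ev %in% ids))
    expect_equal(t$n, nrow(cs$cases))
    # vectorized path agrees with the single-table path
    row <- res$signals[res$signals$drug_name == d, ]
    expect_equal(c(row$a, row$b, row$c, row$d),
                 c(t$a, t$b, t$c, t$d))
  }
})
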