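one_record <- function(beta_exp, beta_out, se_out, se_exp = 0.01) {
  data.frame(variant_id = "rs1", effect_allele = "A", other_allele = "G",
             eaf_exposure = 0.3, beta_exposure = beta_exp, se_exposure = se_exp,
             pval_exposure = NA, n_exposure = 1e5, eaf_outcome = 0.3,
             beta_outcome = beta_out, se_outcome = se_out, pval_outcome = NA,
             n_outcome = 1e5, stringsAsFactors = FALSE)
}

test_that("Wald ratio follows the delta-method formula and propagates signs", {
  est <- mr_wald_ratio(one_record(0.2, 0.1, 0.02))
  expect_equal(est$beta, 0.5)
  expect_equal(est$se, 0.1)
  expect_equal(est$ci_low, 0.5 - qnorm(0.975) * 0.1)
  expect_equal(est$ci_high, 0.5 + qnorm(0.975) * 0.1)

  expect_equal(mr_wald_ratio(one_record(0.2, 0, 0.02))$beta, 0)
  expect_equal(mr_wald_ratio(one_record(0.2, 0, 0.02))$se, 0.1)
  expect_lt(mr_wald_ratio(one_record(-0.2, 0.1, 0.02))$beta, 0)
  expect_error(mr_wald_ratio(one_record(0, 0.1, 0.02)),
               class = "mrcore_estimation_error")
})

test_that("IVW equals weighted least squares through the origin and handles edge cases", {
  records <- make_instruments(50, seed = 8)
  est <- mr_ivw(records, mode = "fixed")
  fit <- lm(beta_outcome ~ 0 + beta_exposure, data = records,
            weights = 1 / records$se_outcome^2)
  expect_equal(est$beta, unname(coef(fit)), tolerance = 1e-10)

  # two identical ratios -> Q = 0, random-effects inflation inactive
  rec2 <- rbind(one_record(0.2, 0.06, 0.02), one_record(0.1, 0.03, 0.02))
  rec2$variant_id <- c("rs1", "rs2")
  est2 <- mr_ivw(rec2)
  expect_equal(est2$beta, 0.3)
  expect_equal(est2$heterogeneity_q, 0)

  # single instrument delegates to the Wald ratio
  expect_equal(mr_ivw(one_record(0.2, 0.1, 0.02))$beta,
               mr_wald_ratio(one_record(0.2, 0.1, 0.02))$beta)
  expect_equal(mr_ivw(one_record(0.2, 0.1, 0.02))$se,
               mr_wald_ratio(one_record(0.2, 0.1, 0.02))$se)

  # random-effects se never below fixed-effect se
  expect_gte(mr_ivw(records, mode = "multiplicative_random")$se,
             mr_ivw(records, mode = "fixed")$se)
  expect_error(mr_ivw(records[0, ]), class = "mrcore_estimation_error")
})

test_that("weighted median matches its cumulative-weight interpolation definition", {
  # equal weights, sorted ratios {0.1, 0.2, 0.9}
  rec <- one_record(1, 0.1, 0.05)
  rec <- rbind(rec, rec, rec)
  rec$variant_id <- c("rs1", "rs2", "rs3")
  rec$beta_outcome <- c(0.1, 0.2, 0.9)
  est <- mr_weighted_median(rec, n_boot = 50, seed = 1)
  r <- ratios_of(rec)
  expect_equal(est$beta, oracle_weighted_median(r$b, 1 / r$se^2))
  expect_equal(est$beta, 0.2)  # symmetric equal-weight case

  # a dominant instrument (>50% of weight) pins the median near its ratio
  rec$se_outcome <- c(0.01, 0.2, 0.2)
  est2 <- mr_weighted_median(rec, n_boot = 50, seed = 1)
  r2 <- ratios_of(rec)
  expect_equal(est2$beta, oracle_weighted_median(r2$b, 1 / r2$se^2))
  expect_lt(abs(est2$beta - 0.1), 0.05)

  # constant ratios -> that constant, with positive bootstrap se
  rec$beta_outcome <- 0.3
  rec$se_outcome <- 0.05
  est3 <- mr_weighted_median(rec, n_boot = 50, seed = 1)
  expect_equal(est3$beta, 0.3)
  expect_gt(est3$se, 0)

  expect_error(mr_weighted_median(rec[1:2, ]),
               class = "mrcore_estimation_error")
})

test_that("weighted mode finds the dominant ratio cluster and breaks ties to the lower mode", {
  # 8 instruments at ratio 0.30, 2 outliers at 1.0, equal weights
  rec <- do.call(rbind, lapply(1:10, function(i) {
    r <- one_record(1, if (i <= 8) 0.3 else 1.0, 0.05)
    r$variant_id <- sprintf("rs%02d", i)
    r
  }))
  # >50% of the weight sits exactly at 0.3, so the weighted MAD (and hence
  # the rule-of-thumb bandwidth) collapses to zero and the epsilon floor kicks in
  expect_warning(est <- mr_weighted_mode(rec, n_boot = 50, seed = 1),
                 "bandwidth")
  r <- ratios_of(rec)
  w <- 1 / r$se^2
  h <- max(mode_bandwidth(r$b, w), 1e-8)
  step <- (diff(range(r$b)) + 6 * h) / 511
  expect_lt(abs(est$beta - oracle_kde_mode(r$b, w, h)), step + 1e-12)
  expect_lte(abs(est$beta - 0.3), 3 * h + 1e-12)

  # all ratios equal -> that value (zero-bandwidth guard)
  recc <- rec
  recc$beta_outcome <- 0.3
  expect_warning(estc <- mr_weighted_mode(recc, n_boot = 20, seed = 1),
                 "bandwidth")
  expect_equal(estc$beta, 0.3, tolerance = 1e-6)

  # two equal-weight symmetric clusters -> the lower mode
  rec2 <- rec
  rec2$beta_outcome <- rep(c(0.2, 0.8), each = 5)
  est2 <- mr_weighted_mode(rec2, n_boot = 20, seed = 1)
  expect_lt(est2$beta, 0.5)

  expect_error(mr_weighted_mode(rec[1:2, ]),
               class = "mrcore_estimation_error")
})

test_that("mean per-instrument F summarizes instrument strength", {
  rec <- one_record(0.05, 0.01, 0.02, se_exp = 0.01)  # z = 5
  expect_equal(mr_f_statistic(rec), 25)
  rec2 <- rbind(rec, one_record(0.03, 0.01, 0.02, se_exp = 0.01))  # z = 3
  rec2$variant_id <- c("rs1", "rs2")
  expect_equal(mr_f_statistic(rec2), 17)
  expect_error(mr_f_statistic(rec[0, ]), class = "mrcore_estimation_error")
})

test_that("estimators are equivariant under outcome and exposure rescaling", {
  records <- make_instruments(12, seed = 9)
  scaled_out <- records
  scaled_out$beta_outcome <- records$beta_outcome * 3
  scaled_out$se_outcome <- records$se_outcome * 3
  scaled_exp <- records
  scaled_exp$beta_exposure <- records$beta_exposure * 2
  scaled_exp$se_exposure <- records$se_exposure * 2

  for (fn in list(
    function(d) mr_ivw(d),
    function(d) mr_weighted_median(d, n_boot = 50, seed = 3))) {
    base <- fn(records)
    out3 <- fn(scaled_out)
    expect_equal(out3$beta, 3 * base$beta, tolerance = 1e-8)
    expect_equal(out3$se, 3 * base$se, tolerance = 1e-8)
    half <- fn(scaled_exp)
    expect_equal(half$beta, base$beta / 2, tolerance = 1e-8)
    expect_equal(half$f_statistic, base$f_statistic, tolerance = 1e-12)
  }

  # the grid argmax makes the mode exact only up to one grid step
  base <- mr_weighted_mode(records, n_boot = 20, seed = 3)
  r <- ratios_of(records)
  step <- (diff(range(r$b)) + 6 * mode_bandwidth(r$b, 1 / r$se^2)) / 511
  out3 <- mr_weighted_mode(scaled_out, n_boot = 20, seed = 3)
  expect_lt(abs(out3$beta - 3 * base$beta), 3 * step + 1e-12)
  half <- mr_weighted_mode(scaled_exp, n_boot = 20, seed = 3)
  expect_lt(abs(half$beta - base$beta / 2), step + 1e-12)
  expect_equal(half$f_statistic, base$f_statistic, tolerance = 1e-12)
})

test_that("bootstrap standard errors are bit-reproducible under a fixed seed", {
  records <- make_instruments(15, seed = 10)
  m1 <- mr_weighted_median(records, n_boot = 200, seed = 77)
  m2 <- mr_weighted_median(records[sample(15), ], n_boot = 200, seed = 77)
  expect_identical(m1$se, m2$se)
  k1 <- mr_weighted_mode(records, n_boot = 100, seed = 77)
  k2 <- mr_weighted_mode(records[sample(15), ], n_boot = 100, seed = 77)
  expect_identical(k1$se, k2$se)
  expect_false(identical(m1$se,
                         mr_weighted_median(records, n_boot = 200, seed = 78)$se))
})
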