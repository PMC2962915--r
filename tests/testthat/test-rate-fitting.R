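test_that("log-linear fit inverts a noiseless exponential exactly", {
  wt <- wt_params()
  tc <- generate_timecourse(wt, NULL, protection_conditions(200),
                            variant = "Wild-type")
  est <- fit_rate_activity(tc)
  expect_equal(est$k, 5.916e-4, tolerance = 1e-4)
  expect_equal(est$k, tc$truth_k, tolerance = 1e-12)
  expect_equal(est$se_k, 0, tolerance = 1e-12)
  expect_equal(est$r_squared, 1)
  expect_equal(est$n_points, 12L)

  # F238S at 500 uM DTNB: k = j*500/(K+500)
  f <- f238s_params()
  tcf <- generate_timecourse(f, NULL, protection_conditions(500),
                             variant = "F238S")
  estf <- fit_rate_activity(tcf)
  expect_equal(estf$k, 7.95e-3 * 500 / 1690, tolerance = 1e-12)
  expect_equal(estf$k, 2.352e-3, tolerance = 1e-4)
})

test_that("degenerate activity inputs are flagged or rejected", {
  flat <- data.frame(time_s = seq(0, 1000, 100), value = 1.0)
  est <- fit_rate_activity(flat)
  expect_identical(est$k, 0)
  expect_equal(est$se_k, 0, tolerance = 1e-12)

  expect_error(fit_rate_activity(
    data.frame(time_s = c(0, 10, 20), value = c(1, -0.1, 0))),
    class = "shprotect_insufficient_data")

  # values clearly rising over time: no inactivation detected
  set.seed(1)
  up <- data.frame(time_s = seq(0, 900, 100),
                   value = exp(0.002 * seq(0, 900, 100)) *
                     (1 + rnorm(10, 0, 0.001)))
  est_up <- fit_rate_activity(up)
  expect_identical(est_up$k, 0)
  expect_true("no_inactivation_detected" %in% est_up$flags)

  # non-positive points are dropped and counted, not clamped
  mixed <- data.frame(time_s = seq(0, 900, 100),
                      value = c(exp(-0.001 * seq(0, 800, 100)), -0.01))
  est_m <- fit_rate_activity(mixed)
  expect_equal(est_m$n_dropped, 1L)
  expect_equal(est_m$k, 0.001, tolerance = 1e-9)
})

test_that("activity fit is invariant to rescaling the values", {
  tc <- data.frame(time_s = seq(0, 3000, 250),
                   value = exp(-7e-4 * seq(0, 3000, 250)))
  a <- fit_rate_activity(tc)
  tc$value <- tc$value * 3.7
  b <- fit_rate_activity(tc)
  expect_equal(a$k, b$k, tolerance = 1e-12)
  expect_equal(a$se_k, b$se_k, tolerance = 1e-10)
})

test_that("absorbance fit recovers rate and plateau from a noiseless trace", {
  sig <- abs_sig(2)
  t <- seq(0, 3 * log(2) / 1e-3, length.out = 40)
  tr <- data.frame(time_s = t, value = a412_signal(1e-3, t, sig))
  est <- fit_rate_absorbance(tr)
  expect_equal(est$k, 1e-3, tolerance = 1e-9)
  expect_equal(est$A_inf, 0.0272, tolerance = 1e-9)

  # fixed plateau, trace truncated at one half-life
  t2 <- seq(0, log(2) / 1e-3, length.out = 15)
  tr2 <- data.frame(time_s = t2, value = a412_signal(1e-3, t2, sig))
  est2 <- fit_rate_absorbance(tr2, sig = sig, fix_Ainf = TRUE)
  expect_equal(est2$k, 1e-3, tolerance = 1e-6)

  expect_error(fit_rate_absorbance(
    data.frame(time_s = t2, value = rep(0, 15))),
    class = "shprotect_insufficient_signal")
  expect_error(fit_rate_absorbance(tr[1:4, ]),
               class = "shprotect_insufficient_data")

  # plateau far below a fixed A_inf is flagged ill-conditioned
  t3 <- seq(0, 0.2 * log(2) / 1e-3, length.out = 15)
  tr3 <- data.frame(time_s = t3, value = a412_signal(1e-3, t3, sig))
  est3 <- fit_rate_absorbance(tr3, sig = sig, fix_Ainf = TRUE)
  expect_true("ill_conditioned" %in% est3$flags)
  expect_equal(est3$k, 1e-3, tolerance = 1e-6)
})

test_that("mode agreement report compares like with like", {
  wt <- wt_params()
  cond <- protection_conditions(200)
  sig <- abs_sig(2)
  ea <- fit_rate_activity(generate_timecourse(wt, NULL, cond))
  eb <- fit_rate_absorbance(generate_timecourse(wt, NULL, cond, sig = sig))
  rep0 <- compare_modes(ea, eb)
  expect_equal(rep0$ratio, 1, tolerance = 1e-9)
  expect_true(rep0$pass)

  # a 10% discrepancy with tight SEs fails
  eb2 <- eb; eb2$k <- eb$k * 1.10; eb2$se_k <- eb$k * 1e-3
  ea2 <- ea; ea2$se_k <- ea$k * 1e-3
  expect_false(compare_modes(ea2, eb2)$pass)

  # mismatched conditions are a usage error
  other <- fit_rate_activity(
    generate_timecourse(wt, NULL, protection_conditions(400)))
  expect_error(compare_modes(other, eb), class = "shprotect_usage_error")
  expect_error(compare_modes(ea, ea), class = "shprotect_usage_error")
})

test_that("mode agreement holds for most noisy replicate pairs", {
  wt <- wt_params()
  cond <- protection_conditions(200)
  sig <- abs_sig(2)
  passes <- 0L
  for (i in 1:100) {
    na <- noise_spec("multiplicative_gaussian", 0.02, seed = 1000L + i)
    nb <- noise_spec("additive_gaussian", 0.002, seed = 2000L + i)
    ea <- fit_rate_activity(generate_timecourse(wt, NULL, cond, noise = na))
    eb <- fit_rate_absorbance(
      generate_timecourse(wt, NULL, cond, sig = sig, noise = nb))
    if (compare_modes(ea, eb)$pass) passes <- passes + 1L
  }
  expect_gte(passes, 90L)
})

test_that("reported fit SE tracks the replicate-to-replicate spread", {
  wt <- wt_params()
  cond <- protection_conditions(200)
  ks <- ses <- numeric(200)
  for (i in 1:200) {
    n <- noise_spec("multiplicative_gaussian", 0.02, seed = 5000L + i)
    est <- fit_rate_activity(generate_timecourse(wt, NULL, cond, noise = n))
    ks[i] <- est$k; ses[i] <- est$se_k
  }
  expect_equal(mean(ks), k_inactivation(wt, 200), tolerance = 0.01)
  ratio <- mean(ses) / sd(ks)
  expect_gt(ratio, 0.5)
  expect_lt(ratio, 2)
})

test_that("fit_rates maps a tidy table to a tidy rates table", {
  study <- generate_study(gdh_catalog()["Wild-type"])
  rates <- fit_rates(as.data.frame(study))
  expect_equal(nrow(rates), 6 + 3 * 6)
  expect_true(all(c("variant", "mode", "dtnb_uM", "coenzyme", "co_mM",
                    "k_s", "se_k", "r2", "n_points", "n_dropped",
                    "flags") %in% names(rates)))
  truths <- vapply(study$courses, function(tc) tc$truth_k, numeric(1))
  key <- function(df) paste(df$coenzyme, df$co_mM, df$dtnb_uM)
  truth_df <- data.frame(key = vapply(study$courses, function(tc) {
    paste(tc$coenzyme, tc$co_mM, tc$dtnb_uM)
  }, character(1)), truth = truths)
  merged <- merge(data.frame(key = key(rates), k = rates$k_s), truth_df)
  expect_equal(merged$k, merged$truth, tolerance = 1e-10)
  expect_error(fit_rates(data.frame(time_s = 1, value = 1)),
               class = "shprotect_schema_error")
})
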