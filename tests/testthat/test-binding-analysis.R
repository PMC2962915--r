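test_that("double-reciprocal saturation fit inverts the forward model", {
  grid <- c(50, 100, 200, 300, 400, 600)
  for (p in list(wt_params(), d263k_params())) {
    sat <- fit_saturation(forward_rates(p, grid))
    expect_equal(sat$j, p$j, tolerance = 1e-9)
    expect_equal(sat$K_DTNB_uM, p$K_DTNB_M * 1e6, tolerance = 1e-9)
    expect_equal(sat$r2, 1)
    # nonlinear route agrees on noiseless data
    satn <- fit_saturation(forward_rates(p, grid), method = "nonlinear")
    expect_equal(satn$j, sat$j, tolerance = 1e-7)
    expect_equal(satn$K_DTNB_uM, sat$K_DTNB_uM, tolerance = 1e-7)
  }
})

test_that("saturation fit flags or rejects non-saturating data", {
  # constant rates: no evidence of a saturable step, K_DTNB -> 0
  flat <- data.frame(dtnb_uM = c(100, 200, 400, 800), k_s = 3.5e-3,
                     coenzyme = "none", co_mM = 0, variant = "x")
  sat <- fit_saturation(flat)
  expect_true("degenerate_no_saturation" %in% sat$flags)
  expect_equal(sat$K_DTNB_uM, 0)
  expect_equal(sat$j, 3.5e-3, tolerance = 1e-9)

  # rates proportional to [DTNB]: reciprocal intercept 0, no saturation
  lin <- data.frame(dtnb_uM = c(50, 100, 200, 400), coenzyme = "none",
                    co_mM = 0, variant = "x",
                    k_s = 1e-6 * c(50, 100, 200, 400))
  expect_error(fit_saturation(lin), class = "shprotect_degenerate_fit")

  expect_error(fit_saturation(forward_rates(wt_params(), c(100, 200))),
               class = "shprotect_insufficient_data")
  prot <- forward_protection_rates(wt_params(), wt_nad(), c(0, 0.2, 0.5))
  expect_error(fit_saturation(prot), class = "shprotect_usage_error")
})

test_that("protection fit recovers the dissociation constant exactly", {
  wt <- wt_params()
  sat <- fit_saturation(forward_rates(wt, c(50, 100, 200, 300, 400, 600),
                                      variant = "Wild-type"))
  series <- forward_protection_rates(wt, wt_nad(),
                                     c(0, 0.1, 0.2, 0.5, 1.0, 2.0),
                                     variant = "Wild-type")
  kd <- fit_kd(series, sat)
  expect_equal(kd$Kd_mM, 0.335, tolerance = 1e-9)
  expect_equal(kd$consistency_ratio, 1, tolerance = 1e-9)
  expect_equal(kd$kmax_pred, k_max(wt, 200), tolerance = 1e-9)

  f <- f238s_params()
  satf <- fit_saturation(forward_rates(f, c(50, 100, 200, 300, 400, 600),
                                       variant = "F238S"))
  seriesf <- forward_protection_rates(f, f238s_nadph(),
                                      c(0, 0.5, 1, 2, 4) * 1.30,
                                      variant = "F238S")
  kdf <- fit_kd(seriesf, satf)
  expect_equal(kdf$Kd_mM, 1.30, tolerance = 1e-9)
})

test_that("protection fit rejects misuse and detects non-binding ligands", {
  wt <- wt_params()
  sat <- fit_saturation(forward_rates(wt, c(50, 100, 200, 400, 600)))
  series <- forward_protection_rates(wt, wt_nad(), c(0, 0.2, 0.5, 1))
  mixed <- series; mixed$dtnb_uM[2] <- 300
  expect_error(fit_kd(mixed, sat), class = "shprotect_usage_error")
  expect_error(fit_kd(series[1:2, ], sat),
               class = "shprotect_insufficient_data")

  # constant k at k_max: no protection, non-binding sentinel
  flat <- series; flat$k_s <- k_max(wt, 200)
  nb <- fit_kd(flat, sat)
  expect_true(is.infinite(nb$Kd_mM))
  expect_true("non_binding" %in% nb$flags)
  expect_true(is.infinite(nb$binding$Kd_M))
})

test_that("delta-method Kd uncertainty agrees with a parametric bootstrap", {
  wt <- wt_params()
  grid <- c(50, 100, 200, 300, 400, 600)
  noise <- noise_spec("multiplicative_gaussian", 0.02, seed = 314L)
  study <- generate_study(
    list(`Wild-type` = list(params = wt,
                            coenzymes = list(`NAD+` = wt_nad()))),
    experiment_design(dtnb_grid = grid), noise)
  rates <- fit_rates(as.data.frame(study))
  sat <- fit_saturation(rates[rates$coenzyme == "none", ])
  series <- rates[rates$coenzyme == "NAD+", ]
  kd <- fit_kd(series, sat)
  boot <- kd_bootstrap_se(series, sat, n_boot = 500, seed = 271L)
  ratio <- kd$se_Kd_mM / boot$se_boot
  expect_gt(ratio, 1 / 1.5)
  expect_lt(ratio, 1.5)
})

test_that("discrimination ratios and fold changes reproduce published arithmetic", {
  expect_equal(signif(discrimination_ratio(0.023, 0.024)$ratio, 2), 0.96)
  expect_equal(signif(discrimination_ratio(0.375, 0.052)$ratio, 2), 7.2)
  expect_equal(discrimination_ratio(0.13, 0.13)$ratio, 1.0)
  expect_false(discrimination_ratio(Inf, 0.024)$defined)

  expect_equal(signif(fold_change(2.84, 0.335)$fold, 2), 8.5)
  expect_equal(signif(fold_change(0.375, 0.023)$fold, 2), 16)
  expect_equal(fold_change(0.13, 0.13)$fold, 1.0)
  expect_error(fold_change(1, 0), class = "shprotect_domain_error")

  # delta-method SE of a ratio of independent estimates
  r <- discrimination_ratio(0.023, 0.024, 0.001, 0.001)
  expect_equal(r$se, (0.023 / 0.024) *
                 sqrt((0.001 / 0.023)^2 + (0.001 / 0.024)^2))
})

test_that("comparison table assembles folds and discrimination across variants", {
  cat5 <- gdh_catalog()
  results <- list()
  for (v in names(cat5)) {
    p <- cat5[[v]]$params
    sat <- fit_saturation(forward_rates(p, c(50, 100, 200, 300, 400, 600),
                                        variant = v))
    for (b in cat5[[v]]$coenzymes) {
      series <- forward_protection_rates(
        p, b, c(0, 0.25, 0.5, 1, 2, 4) * b$Kd_M * 1e3, variant = v)
      results[[paste(v, b$coenzyme)]] <- fit_kd(series, sat)
    }
  }
  tab <- build_comparison_table(results, "Wild-type")
  expect_equal(nrow(tab$kd), 15)
  expect_equal(nrow(tab$discrimination), 5)
  disc <- setNames(tab$discrimination$ratio_NADPH_NADH,
                   tab$discrimination$variant)
  published <- c(`Wild-type` = 0.96, F238S = 5.6, P262S = 7.2,
                 `F238S/P262S` = 2.1, D263K = 1.75)
  expect_equal(signif(disc[names(published)], 2), signif(published, 2))
  wt_rows <- tab$kd[tab$kd$variant == "Wild-type", ]
  expect_equal(wt_rows$fold_change, rep(1, 3), tolerance = 1e-9)

  single <- build_comparison_table(results["Wild-type NAD+"], "Wild-type")
  expect_equal(nrow(single$kd), 1)
  expect_error(build_comparison_table(results, "nonexistent"),
               class = "shprotect_usage_error")
  expect_error(
    build_comparison_table(c(results, results["Wild-type NAD+"]),
                           "Wild-type"),
    class = "shprotect_usage_error")
})
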