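# Stage 2: from fitted rate constants to binding constants.
#
# Saturation stage: 1/k is regressed on 1/[DTNB]; the ordinate intercept is
# 1/j and the slope/intercept ratio is K_DTNB. Protection stage: 1/k_Co is
# regressed on [Co]; the slope (1/j)(K_DTNB/[DTNB])(1/Kd) yields Kd given
# the saturation-stage constants, and the intercept must reproduce the
# unprotected rate at the working [DTNB] (the consistency ratio reported on
# every fit). Standard errors propagate by the delta method assuming
# independence of the slope SE and the baseline-parameter SEs.

as_rates_df <- function(rates) {
  if (inherits(rates, "rate_estimate")) rates <- list(rates)
  if (is.list(rates) && !is.data.frame(rates) &&
      all(vapply(rates, inherits, logical(1), "rate_estimate"))) {
    rates <- do.call(rbind, lapply(rates, as.data.frame))
  }
  as.data.frame(rates)
}

#' Fit the DTNB saturation law to a set of unprotected rate constants
#'
#' Default method: unweighted double-reciprocal regression of `1/k` on
#' `1/[DTNB]`, giving `j = 1/intercept` and `K_DTNB = slope/intercept`, with
#' standard errors from the regression covariance by the delta method. The
#' `"nonlinear"` method fits `k = j [DTNB]/(K_DTNB + [DTNB])` directly by
#' Levenberg-Marquardt least squares (started from the reciprocal fit); the
#' two agree exactly on noiseless data.
#'
#' A slope not distinguishable from zero (constant rates: no evidence of a
#' saturable binding step) is returned with `K_DTNB = 0` and a
#' `"degenerate_no_saturation"` flag rather than an error; a non-positive
#' intercept (rates still rising linearly: no saturation in the sampled
#' range) is an error.
#'
#' @param rates a rates table (see [fit_rates]) restricted to
#'   coenzyme-free series, or a list of `rate_estimate` objects. Requires
#'   at least three distinct DTNB levels.
#' @param method `"double_reciprocal"` (default) or `"nonlinear"`.
#' @return an object of class `saturation_fit` with elements `j`, `se_j`,
#'   `K_DTNB_uM`, `se_K_uM`, `params`, `line` (reciprocal-line coefficients
#'   and covariance), `r2`, `variant`, `method`, `flags`.
#' @export
fit_saturation <- function(rates, method = c("double_reciprocal",
                                             "nonlinear")) {
  method <- match.arg(method)
  df <- as_rates_df(rates)
  stopifnot(all(c("dtnb_uM", "k_s") %in% names(df)))
  if ("co_mM" %in% names(df) && any(df$co_mM > 0)) {
    stop_shprotect("saturation fit requires coenzyme-free rates",
                   "shprotect_usage_error")
  }
  df <- df[is.finite(df$k_s) & df$k_s > 0 & df$dtnb_uM > 0, ]
  if (length(unique(df$dtnb_uM)) < 3) {
    stop_shprotect("need rates at >= 3 distinct DTNB levels",
                   "shprotect_insufficient_data")
  }
  variant <- if ("variant" %in% names(df)) df$variant[1] else "enzyme"
  x <- 1 / df$dtnb_uM
  y <- 1 / df$k_s
  fit <- lm(y ~ x)
  a <- unname(coef(fit)[1])          # 1/j, s
  b <- unname(coef(fit)[2])          # K_DTNB/j, s uM
  V <- quiet_vcov(fit)
  se_a <- sqrt(V[1, 1])
  se_b <- sqrt(V[2, 2])
  r2 <- r_squared(y, fitted(fit))
  if (a <= 0) {
    stop_shprotect(
      "non-positive reciprocal intercept: data do not show saturation",
      "shprotect_degenerate_fit")
  }
  flags <- character()
  if (b <= 2 * se_b) {
    # constant rates across levels: K_DTNB -> 0 limit
    flags <- "degenerate_no_saturation"
    out <- structure(list(j = 1 / a, se_j = se_a / a^2, K_DTNB_uM = 0,
                          se_K_uM = NA_real_, params = NULL,
                          line = list(intercept = a, slope = b,
                                      se_intercept = se_a, se_slope = se_b,
                                      cov = V),
                          r2 = r2, n_levels = length(unique(df$dtnb_uM)),
                          variant = variant, method = method, flags = flags),
                     class = "saturation_fit")
    return(out)
  }
  j <- 1 / a
  K <- b / a
  se_j <- se_a / a^2
  # delta method for K = b/a with the full regression covariance
  grad <- c(-b / a^2, 1 / a)
  se_K <- sqrt(drop(t(grad) %*% V %*% grad))
  if (method == "nonlinear") {
    nfit <- nlsLM(k_s ~ j * dtnb_uM / (K + dtnb_uM), data = df,
                  start = list(j = j, K = K), lower = c(j = 0, K = 0),
                  control = minpack.lm::nls.lm.control(maxiter = 200))
    est <- coef(nfit)
    ses <- tryCatch(sqrt(diag(vcov(nfit))),
                    error = function(e) c(j = NA_real_, K = NA_real_))
    j <- unname(est["j"]); K <- unname(est["K"])
    se_j <- unname(ses[["j"]]); se_K <- unname(ses[["K"]])
    r2 <- r_squared(df$k_s, fitted(nfit))
  }
  structure(list(j = j, se_j = se_j, K_DTNB_uM = K, se_K_uM = se_K,
                 params = inactivation_params(j, K),
                 line = list(intercept = a, slope = b, se_intercept = se_a,
                             se_slope = se_b, cov = V),
                 r2 = r2, n_levels = length(unique(df$dtnb_uM)),
                 variant = variant, method = method, flags = flags),
            class = "saturation_fit")
}

#' @export
print.saturation_fit <- function(x, ...) {
  cat(sprintf(
    "<saturation_fit> %s (%s): j = %.4g +/- %.2g s^-1, K_DTNB = %.4g +/- %.2g uM%s\n",
    x$variant, x$method, x$j, x$se_j, x$K_DTNB_uM, x$se_K_uM,
    if (length(x$flags)) paste0(" [", paste(x$flags, collapse = ","), "]")
    else ""))
  invisible(x)
}

#' @export
as.data.frame.saturation_fit <- function(x, ...) {
  data.frame(variant = x$variant, j_s = x$j, se_j = x$se_j,
             K_DTNB_uM = x$K_DTNB_uM, se_K_uM = x$se_K_uM,
             method = x$method, r2 = x$r2, n_levels = x$n_levels,
             flags = paste(x$flags, collapse = ";"),
             stringsAsFactors = FALSE)
}

#' Fit a coenzyme dissociation constant from a protection series
#'
#' Unweighted regression of `1/k_Co` on `[Co]` at fixed working DTNB
#' concentration. The dissociation constant follows from the slope:
#' `Kd = (1/j)(K_DTNB/[DTNB]) / slope` (mM when the slope is per mM), using
#' the baseline parameters of the supplied saturation fit. The standard
#' error combines the relative SEs of the slope, `j` and `K_DTNB` by the
#' delta method under independence. The reciprocal intercept is compared
#' with the unprotected rate predicted at the working DTNB concentration;
#' their ratio (`consistency_ratio`) should be 1.
#'
#' A slope not distinguishable from zero at two SEs (no measurable
#' protection) returns the explicit non-binding sentinel (`Kd = Inf`) with a
#' `"non_binding"` flag.
#'
#' @param series rates table rows for one variant/coenzyme pair at a single
#'   DTNB concentration, with at least three distinct ligand levels
#'   (columns `co_mM`, `k_s`, and optionally `se_k`, `dtnb_uM`, `variant`,
#'   `coenzyme`).
#' @param sat the [fit_saturation] result for the same variant.
#' @param dtnb_uM working DTNB concentration; defaults to the series'
#'   `dtnb_uM` column, which must be constant.
#' @return an object of class `kd_result`.
#' @export
fit_kd <- function(series, sat, dtnb_uM = NULL) {
  stopifnot(inherits(sat, "saturation_fit"))
  if (is.null(sat$params)) {
    stop_shprotect("saturation fit is degenerate; cannot convert slope to Kd",
                   "shprotect_degenerate_fit")
  }
  df <- as_rates_df(series)
  stopifnot(all(c("co_mM", "k_s") %in% names(df)))
  if ("dtnb_uM" %in% names(df)) {
    levels_d <- unique(df$dtnb_uM)
    if (length(levels_d) > 1) {
      stop_shprotect("protection series mixes DTNB concentrations",
                     "shprotect_usage_error")
    }
    dtnb_uM <- dtnb_uM %||% levels_d
  }
  if (is.null(dtnb_uM) || !(dtnb_uM > 0)) {
    stop_shprotect("working dtnb_uM must be supplied and positive",
                   "shprotect_usage_error")
  }
  variant <- if ("variant" %in% names(df)) df$variant[1] else sat$variant
  if (!is.null(sat$variant) && "variant" %in% names(df) &&
      !identical(variant, sat$variant)) {
    stop_shprotect("saturation fit and protection series are from different variants",
                   "shprotect_usage_error")
  }
  coenzyme <- if ("coenzyme" %in% names(df)) df$coenzyme[1] else "ligand"
  df <- df[is.finite(df$k_s) & df$k_s > 0, ]
  if (length(unique(df$co_mM)) < 3) {
    stop_shprotect("need rates at >= 3 distinct coenzyme levels",
                   "shprotect_insufficient_data")
  }
  y <- 1 / df$k_s
  fit <- lm(y ~ co_mM, data = df)
  a <- unname(coef(fit)[1])  # s
  b <- unname(coef(fit)[2])  # s / mM
  V <- quiet_vcov(fit)
  se_a <- sqrt(V[1, 1]); se_b <- sqrt(V[2, 2])
  r2 <- r_squared(y, fitted(fit))
  kmax_expected <- k_inactivation(sat$params, dtnb_uM)
  base <- list(variant = variant, coenzyme = coenzyme, dtnb_uM = dtnb_uM,
               slope = b, se_slope = se_b, intercept = a,
               se_intercept = se_a, r2 = r2,
               n_levels = length(unique(df$co_mM)),
               kmax_expected = kmax_expected)
  if (b <= 2 * se_b) {
    return(structure(c(base, list(
      binding = non_binding(coenzyme), Kd_mM = Inf, se_Kd_mM = NA_real_,
      kmax_pred = if (a > 0) 1 / a else NA_real_,
      consistency_ratio = if (a > 0) (1 / a) / kmax_expected else NA_real_,
      flags = "non_binding")), class = "kd_result"))
  }
  if (a <= 0) {
    stop_shprotect("non-positive protection-line intercept: degenerate fit",
                   "shprotect_degenerate_fit")
  }
  K_uM <- sat$K_DTNB_uM
  Kd <- (1 / sat$j) * (K_uM / dtnb_uM) / b   # mM
  rel2 <- (se_b / b)^2 +
    (if (is.finite(sat$se_j)) (sat$se_j / sat$j)^2 else 0) +
    (if (is.finite(sat$se_K_uM)) (sat$se_K_uM / K_uM)^2 else 0)
  se_Kd <- Kd * sqrt(rel2)
  kmax_pred <- 1 / a
  structure(c(base, list(
    binding = coenzyme_binding(coenzyme, Kd),
    Kd_mM = Kd, se_Kd_mM = se_Kd, kmax_pred = kmax_pred,
    consistency_ratio = kmax_pred / kmax_expected,
    flags = character())), class = "kd_result")
}

#' @export
print.kd_result <- function(x, ...) {
  if (is.infinite(x$Kd_mM)) {
    cat(sprintf("<kd_result> %s + %s: non-binding (no protection)\n",
                x$variant, x$coenzyme))
  } else {
    cat(sprintf(
      "<kd_result> %s + %s: Kd = %.4g +/- %.2g mM (consistency %.4f)\n",
      x$variant, x$coenzyme, x$Kd_mM, x$se_Kd_mM, x$consistency_ratio))
  }
  invisible(x)
}

#' @export
as.data.frame.kd_result <- function(x, ...) {
  data.frame(variant = x$variant, coenzyme = x$coenzyme,
             dtnb_uM = x$dtnb_uM, Kd_mM = x$Kd_mM, se_Kd_mM = x$se_Kd_mM,
             slope = x$slope, se_slope = x$se_slope,
             intercept = x$intercept, se_intercept = x$se_intercept,
             kmax_pred = x$kmax_pred, kmax_expected = x$kmax_expected,
             consistency_ratio = x$consistency_ratio, r2 = x$r2,
             n_levels = x$n_levels,
             flags = paste(x$flags, collapse = ";"),
             stringsAsFactors = FALSE)
}

kd_value <- function(x) {
  if (inherits(x, "kd_result")) x$Kd_mM else x
}
kd_se <- function(x, se) {
  if (inherits(x, "kd_result")) x$se_Kd_mM else se
}

#' Discrimination ratio between the reduced coenzymes
#'
#' `Kd(NADPH) / Kd(NADH)`: the binding preference of a variant for NADH over
#' NADPH. Reported alongside a delta-method SE when input SEs are available.
#' A non-binding sentinel on either side yields an undefined ratio.
#'
#' @param kd_nadph,kd_nadh dissociation constants in mM, or `kd_result`
#'   objects.
#' @param se_nadph,se_nadh optional standard errors (ignored when
#'   `kd_result` objects are supplied).
#' @return list with `ratio`, `se`, and `defined`.
#' @examples
#' discrimination_ratio(0.023, 0.024)$ratio  # 0.96 at 2 s.f.
#' @export
discrimination_ratio <- function(kd_nadph, kd_nadh,
                                 se_nadph = NA_real_, se_nadh = NA_real_) {
  p <- kd_value(kd_nadph); h <- kd_value(kd_nadh)
  se_p <- kd_se(kd_nadph, se_nadph); se_h <- kd_se(kd_nadh, se_nadh)
  if (!is.finite(p) || !is.finite(h) || p <= 0 || h <= 0) {
    return(list(ratio = NA_real_, se = NA_real_, defined = FALSE))
  }
  ratio <- p / h
  se <- if (is.finite(se_p) && is.finite(se_h)) {
    ratio * sqrt((se_p / p)^2 + (se_h / h)^2)
  } else {
    NA_real_
  }
  list(ratio = ratio, se = se, defined = TRUE)
}

#' Fold change of a dissociation constant relative to a reference variant
#'
#' @param kd_variant,kd_reference dissociation constants in mM (or
#'   `kd_result` objects); the reference must be positive and finite.
#' @param se_variant,se_reference optional standard errors.
#' @return list with `fold` and `se`.
#' @examples
#' fold_change(2.84, 0.335)$fold  # 8.5 at 2 s.f.
#' @export
fold_change <- function(kd_variant, kd_reference,
                        se_variant = NA_real_, se_reference = NA_real_) {
  v <- kd_value(kd_variant); r <- kd_value(kd_reference)
  se_v <- kd_se(kd_variant, se_variant)
  se_r <- kd_se(kd_reference, se_reference)
  if (!is.finite(r) || r <= 0) {
    stop_shprotect("reference Kd must be positive and finite",
                   "shprotect_domain_error")
  }
  if (!is.finite(v)) return(list(fold = Inf, se = NA_real_))
  fold <- v / r
  se <- if (is.finite(se_v) && is.finite(se_r)) {
    fold * sqrt((se_v / v)^2 + (se_r / r)^2)
  } else {
    NA_real_
  }
  list(fold = fold, se = se)
}

#' Comparative table of dissociation constants across variants
#'
#' Assembles per-variant, per-coenzyme dissociation constants with fold
#' changes relative to a designated reference variant, and the NADPH/NADH
#' discrimination ratio for every variant carrying both reduced coenzymes.
#' Missing (variant, coenzyme) combinations are simply absent; non-binding
#' sentinels propagate as `Inf` with undefined ratios.
#'
#' @param results list of `kd_result` objects (or a data frame in the
#'   [as.data.frame.kd_result] layout).
#' @param reference variant identifier used as the fold-change baseline.
#' @return an object of class `comparison_table`: list with `kd` (long data
#'   frame: variant, coenzyme, Kd_mM, se_Kd_mM, fold_change),
#'   `discrimination` (variant, ratio_NADPH_NADH, se), and `reference`.
#' @export
build_comparison_table <- function(results, reference) {
  df <- if (is.data.frame(results)) results
        else do.call(rbind, lapply(results, as.data.frame))
  stopifnot(all(c("variant", "coenzyme", "Kd_mM") %in% names(df)))
  if (!"se_Kd_mM" %in% names(df)) df$se_Kd_mM <- NA_real_
  if (anyDuplicated(df[, c("variant", "coenzyme")])) {
    stop_shprotect("duplicate (variant, coenzyme) entries",
                   "shprotect_usage_error")
  }
  if (!reference %in% df$variant) {
    stop_shprotect(sprintf("reference variant '%s' not among results",
                           reference), "shprotect_usage_error")
  }
  ref <- df[df$variant == reference, ]
  fold <- mapply(function(v, co, kd, se) {
    r <- ref[ref$coenzyme == co, ]
    if (nrow(r) == 0 || !is.finite(r$Kd_mM) || r$Kd_mM <= 0) return(NA_real_)
    kd / r$Kd_mM
  }, df$variant, df$coenzyme, df$Kd_mM, df$se_Kd_mM)
  kd_tab <- data.frame(variant = df$variant, coenzyme = df$coenzyme,
                       Kd_mM = df$Kd_mM, se_Kd_mM = df$se_Kd_mM,
                       fold_change = unname(fold),
                       stringsAsFactors = FALSE)
  variants <- unique(df$variant)
  disc <- do.call(rbind, lapply(variants, function(v) {
    p <- df[df$variant == v & df$coenzyme == "NADPH", ]
    h <- df[df$variant == v & df$coenzyme == "NADH", ]
    if (nrow(p) == 0 || nrow(h) == 0) return(NULL)
    r <- discrimination_ratio(p$Kd_mM, h$Kd_mM, p$se_Kd_mM, h$se_Kd_mM)
    data.frame(variant = v, ratio_NADPH_NADH = r$ratio, se = r$se,
               stringsAsFactors = FALSE)
  }))
  structure(list(kd = kd_tab, discrimination = disc, reference = reference),
            class = "comparison_table")
}

#' @export
print.comparison_table <- function(x, digits = 2, ...) {
  cat(sprintf("Dissociation constants (reference variant: %s)\n",
              x$reference))
  tab <- x$kd
  tab$Kd_mM <- signif(tab$Kd_mM, 3)
  tab$se_Kd_mM <- signif(tab$se_Kd_mM, 2)
  tab$fold_change <- signif(tab$fold_change, digits)
  print(tab, row.names = FALSE)
  if (!is.null(x$discrimination)) {
    cat("\nNADPH/NADH discrimination:\n")
    d <- x$discrimination
    d$ratio_NADPH_NADH <- signif(d$ratio_NADPH_NADH, 2)
    d$se <- signif(d$se, 2)
    print(d, row.names = FALSE)
  }
  invisible(x)
}

#' Parametric-bootstrap standard error for a protection-stage Kd
#'
#' Cross-check on the delta-method SE reported by [fit_kd]: resamples each
#' observed rate constant from a normal distribution centred on its estimate
#' with its fitted SE, perturbs the baseline parameters by their SEs, refits
#' the protection line, and returns the SD of the resampled Kd values.
#'
#' @param series,sat as in [fit_kd]; the series must carry an `se_k` column.
#' @param n_boot number of resamples.
#' @param seed RNG seed (local; global RNG state is restored).
#' @return list with `se_boot` and the vector of resampled `Kd` values.
#' @export
kd_bootstrap_se <- function(series, sat, n_boot = 500, seed = NULL) {
  df <- as_rates_df(series)
  stopifnot("se_k" %in% names(df), all(is.finite(df$se_k)))
  with_local_seed(seed, {
    kds <- vapply(seq_len(n_boot), function(i) {
      d <- df
      d$k_s <- rnorm(nrow(d), d$k_s, d$se_k)
      j_b <- rnorm(1, sat$j, if (is.finite(sat$se_j)) sat$se_j else 0)
      K_b <- rnorm(1, sat$K_DTNB_uM,
                   if (is.finite(sat$se_K_uM)) sat$se_K_uM else 0)
      d <- d[d$k_s > 0, ]
      if (nrow(d) < 3 || j_b <= 0 || K_b <= 0) return(NA_real_)
      b <- unname(coef(lm(I(1 / k_s) ~ co_mM, data = d))[2])
      if (b <= 0) return(NA_real_)
      (1 / j_b) * (K_b / d$dtnb_uM[1]) / b
    }, numeric(1))
    list(se_boot = sd(kds, na.rm = TRUE), Kd = kds)
  })
}
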