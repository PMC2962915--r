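# Stage 1: pseudo-first-order rate estimation from a single time course.

as_tc_df <- function(tc) {
  if (inherits(tc, "time_course")) {
    return(data.frame(time_s = tc$times, value = tc$values))
  }
  df <- as.data.frame(tc)
  if (all(c("time_s", "value") %in% names(df))) {
    return(df[, c("time_s", "value")])
  }
  if (all(c("times", "values") %in% names(df))) {
    return(data.frame(time_s = df$times, value = df$values))
  }
  stop_shprotect("time course needs columns time_s and value",
                 "shprotect_usage_error")
}

tc_meta <- function(tc) {
  if (inherits(tc, "time_course")) {
    list(variant = tc$variant, dtnb_uM = tc$dtnb_uM,
         coenzyme = tc$coenzyme, co_mM = tc$co_mM,
         replicate = tc$replicate)
  } else {
    df <- as.data.frame(tc)
    grab <- function(col, default) {
      if (col %in% names(df)) df[[col]][1] else default
    }
    list(variant = grab("variant", "enzyme"),
         dtnb_uM = grab("dtnb_uM", NA_real_),
         coenzyme = grab("coenzyme", "none"),
         co_mM = grab("co_mM", 0),
         replicate = grab("replicate", 1L))
  }
}

new_rate_estimate <- function(k, se_k, r2, n_points, n_dropped, mode, meta,
                              flags = character(), extra = list()) {
  structure(c(list(k = k, se_k = se_k, r_squared = r2,
                   n_points = n_points, n_dropped = n_dropped,
                   mode = mode, flags = flags), meta, extra),
            class = "rate_estimate")
}

#' @export
print.rate_estimate <- function(x, ...) {
  cat(sprintf(
    "<rate_estimate> k = %.4g +/- %.2g s^-1 (%s, n = %d, R2 = %.4f)%s\n",
    x$k, x$se_k, x$mode, x$n_points, x$r_squared,
    if (length(x$flags)) paste0(" [", paste(x$flags, collapse = ", "), "]")
    else ""))
  invisible(x)
}

#' @export
as.data.frame.rate_estimate <- function(x, ...) {
  data.frame(variant = x$variant, mode = x$mode, dtnb_uM = x$dtnb_uM,
             coenzyme = x$coenzyme, co_mM = x$co_mM,
             replicate = x$replicate, k_s = x$k, se_k = x$se_k,
             r2 = x$r_squared, n_points = x$n_points,
             n_dropped = x$n_dropped,
             flags = paste(x$flags, collapse = ";"),
             stringsAsFactors = FALSE)
}

#' Fit a pseudo-first-order rate constant from an activity time course
#'
#' Unweighted linear regression of `log(activity)` on time; the rate
#' constant is the negated slope and its standard error is the slope's
#' regression SE. Non-positive activity values (possible under additive
#' noise) are dropped, not clamped, and the dropped count is carried on the
#' estimate. A fitted slope that is positive by more than twice its SE is
#' reported as `k = 0` with a `"no_inactivation_detected"` flag; a positive
#' slope within noise is clipped to zero with a `"clipped_to_zero"` flag.
#' R-squared is reported on the log scale and is diagnostic only.
#'
#' @param tc a `time_course` in activity mode, or a data frame with columns
#'   `time_s` and `value`.
#' @return an object of class `rate_estimate`.
#' @export
fit_rate_activity <- function(tc) {
  meta <- tc_meta(tc)
  df <- as_tc_df(tc)
  if (inherits(tc, "time_course") && tc$mode != "activity") {
    stop_shprotect("fit_rate_activity requires an activity-mode course",
                   "shprotect_usage_error")
  }
  usable <- is.finite(df$value) & df$value > 0
  n_dropped <- sum(!usable)
  df <- df[usable, ]
  if (nrow(df) < 3) {
    stop_shprotect("fewer than 3 usable (positive) activity points",
                   "shprotect_insufficient_data")
  }
  fit <- lm(log(value) ~ time_s, data = df)
  slope <- unname(coef(fit)[2])
  se <- sqrt(diag(quiet_vcov(fit)))[2]
  r2 <- r_squared(log(df$value), fitted(fit))
  flags <- character()
  k <- -slope
  if (slope > 0) {
    flags <- if (is.finite(se) && slope > 2 * se) "no_inactivation_detected"
             else "clipped_to_zero"
    k <- 0
  }
  new_rate_estimate(k, unname(se), r2, nrow(df), n_dropped, "activity",
                    meta, flags)
}

#' Fit a rate constant from an A412 absorbance trace
#'
#' Fits the exponential rise `A(t) = A_inf (1 - exp(-k t))`. By default both
#' `A_inf` and `k` are estimated by nonlinear least squares (robust to
#' pipetting error in the -SH concentration); with `fix_Ainf = TRUE` the
#' plateau is fixed at `eps * l * [SH]0` from the signal model and the fit
#' reduces to a log-linear regression of `log(1 - A/A_inf)` on time. A trace
#' whose highest point is below half of a fixed plateau carries an
#' `"ill_conditioned"` flag.
#'
#' @param tc a `time_course` in absorbance mode, or a data frame with
#'   columns `time_s` and `value`.
#' @param sig a [signal_model]; required when `fix_Ainf = TRUE`.
#' @param fix_Ainf fix the plateau from the signal model instead of
#'   co-estimating it.
#' @return an object of class `rate_estimate` with an `A_inf` element.
#' @export
fit_rate_absorbance <- function(tc, sig = NULL, fix_Ainf = FALSE) {
  meta <- tc_meta(tc)
  df <- as_tc_df(tc)
  if (inherits(tc, "time_course") && tc$mode != "absorbance") {
    stop_shprotect("fit_rate_absorbance requires an absorbance-mode course",
                   "shprotect_usage_error")
  }
  df <- df[is.finite(df$value), ]
  if (nrow(df) < 5) {
    stop_shprotect("fewer than 5 absorbance points",
                   "shprotect_insufficient_data")
  }
  if (max(df$value) <= 0) {
    stop_shprotect("no signal in trace (all values <= 0)",
                   "shprotect_insufficient_signal")
  }
  flags <- character()
  if (fix_Ainf) {
    if (is.null(sig) || sig$mode != "absorbance") {
      stop_shprotect("fix_Ainf = TRUE requires an absorbance signal_model",
                     "shprotect_config_error")
    }
    A_inf <- sig$extinction_coeff * sig$path_length * sig$sh_conc_uM / 1e3
    if (max(df$value) < 0.5 * A_inf) flags <- c(flags, "ill_conditioned")
    sub <- df[df$value < A_inf, ]
    if (nrow(sub) < 3) {
      stop_shprotect("too few points below the fixed plateau",
                     "shprotect_insufficient_data")
    }
    y <- log(1 - sub$value / A_inf)
    fit <- lm(y ~ sub$time_s)
    k <- -unname(coef(fit)[2])
    se <- unname(sqrt(diag(quiet_vcov(fit)))[2])
    r2 <- r_squared(y, fitted(fit))
    return(new_rate_estimate(max(0, k), se, r2, nrow(sub),
                             nrow(df) - nrow(sub), "absorbance", meta,
                             flags, list(A_inf = A_inf)))
  }
  # Co-estimate plateau and rate: start values from a crude plateau guess
  # and the corresponding log-linear slope.
  A0 <- max(df$value) * 1.05
  early <- df[df$value < 0.95 * A0 & df$time_s > 0, ]
  k0 <- if (nrow(early) >= 2) {
    max(1e-8, -unname(coef(lm(log(1 - early$value / A0) ~
                                early$time_s))[2]))
  } else {
    1 / max(df$time_s)
  }
  fit <- tryCatch(
    nlsLM(value ~ A_inf * (1 - exp(-k * time_s)), data = df,
          start = list(A_inf = A0, k = k0),
          lower = c(A_inf = 0, k = 0),
          control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) {
      stop_shprotect(
        sprintf("absorbance fit failed to converge (%s, DTNB %g uM): %s",
                meta$variant, meta$dtnb_uM, conditionMessage(e)),
        "shprotect_estimation_error")
    })
  est <- coef(fit)
  ses <- tryCatch(sqrt(diag(vcov(fit))), error = function(e) c(NA, NA))
  r2 <- r_squared(df$value, fitted(fit))
  new_rate_estimate(unname(est["k"]), unname(ses[["k"]]), r2, nrow(df), 0L,
                    "absorbance", meta, flags,
                    list(A_inf = unname(est["A_inf"]),
                         se_A_inf = unname(ses[["A_inf"]])))
}

#' Agreement between activity-mode and absorbance-mode estimates
#'
#' Both observation modes track the same covalent event, so their rate
#' constants should agree. Returns the ratio of the two estimates, its
#' delta-method standard error, and a pass/fail flag: pass when the ratio is
#' within `1 +/- tolerance_mult *` (combined relative SE), with a small
#' absolute floor so that exact noiseless agreement passes.
#'
#' @param a,b `rate_estimate` objects with matching conditions and
#'   different modes.
#' @param tolerance_mult multiplier on the combined relative SE (default 2).
#' @return list with `ratio`, `se_ratio`, `pass`.
#' @export
compare_modes <- function(a, b, tolerance_mult = 2) {
  stopifnot(inherits(a, "rate_estimate"), inherits(b, "rate_estimate"))
  if (a$mode == b$mode) {
    stop_shprotect("compare_modes requires two different observation modes",
                   "shprotect_usage_error")
  }
  same <- isTRUE(all.equal(a$dtnb_uM, b$dtnb_uM)) &&
    identical(a$coenzyme, b$coenzyme) &&
    isTRUE(all.equal(a$co_mM, b$co_mM)) &&
    identical(a$variant, b$variant)
  if (!same) {
    stop_shprotect("compare_modes requires matching conditions",
                   "shprotect_usage_error")
  }
  if (b$k <= 0) {
    stop_shprotect("reference estimate has k = 0; ratio undefined",
                   "shprotect_usage_error")
  }
  ratio <- a$k / b$k
  rel <- sqrt((a$se_k / a$k)^2 + (b$se_k / b$k)^2)
  if (!is.finite(rel)) rel <- Inf
  pass <- abs(ratio - 1) <= max(tolerance_mult * rel, 1e-6)
  list(ratio = ratio, se_ratio = ratio * rel, pass = pass)
}

#' Fit rate constants for every series in a tidy observation table
#'
#' Splits a tidy table (columns `time_s`, `value`, `mode`, `variant`,
#' `dtnb_uM`, `coenzyme`, `co_mM`, and optionally `replicate`) into
#' individual time courses and fits each with the mode-appropriate
#' estimator. Courses that fail to fit are dropped with a warning naming
#' the series.
#'
#' @param df tidy observation table (e.g. from `as.data.frame()` on a study
#'   or [read_timecourses]).
#' @param sig optional [signal_model] for fixed-plateau absorbance fits.
#' @param fix_Ainf passed to [fit_rate_absorbance].
#' @return rates table: one row per course with columns `variant`, `mode`,
#'   `dtnb_uM`, `coenzyme`, `co_mM`, `replicate`, `k_s`, `se_k`, `r2`,
#'   `n_points`, `n_dropped`, `flags`.
#' @export
fit_rates <- function(df, sig = NULL, fix_Ainf = FALSE) {
  df <- as.data.frame(df)
  req <- c("time_s", "value", "mode", "variant", "dtnb_uM", "coenzyme",
           "co_mM")
  missing_cols <- setdiff(req, names(df))
  if (length(missing_cols)) {
    stop_shprotect(paste("missing columns:",
                         paste(missing_cols, collapse = ", ")),
                   "shprotect_schema_error")
  }
  if (!"replicate" %in% names(df)) df$replicate <- 1L
  key <- interaction(df$variant, df$mode, df$dtnb_uM, df$coenzyme,
                     df$co_mM, df$replicate, drop = TRUE)
  groups <- split(df, key)
  rows <- lapply(groups, function(g) {
    g <- g[order(g$time_s), ]
    est <- tryCatch({
      if (g$mode[1] == "activity") fit_rate_activity(g)
      else fit_rate_absorbance(g, sig = sig, fix_Ainf = fix_Ainf)
    }, shprotect_error = function(e) {
      warning(sprintf("series %s/%s (DTNB %g uM, %s %g mM) not fitted: %s",
                      g$variant[1], g$mode[1], g$dtnb_uM[1], g$coenzyme[1],
                      g$co_mM[1], conditionMessage(e)), call. = FALSE)
      NULL
    })
    if (is.null(est)) NULL else as.data.frame(est)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (!length(rows)) {
    stop_shprotect("no series could be fitted", "shprotect_estimation_error")
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out[order(out$variant, out$mode, out$coenzyme, out$co_mM, out$dtnb_uM,
            out$replicate), , drop = FALSE]
}
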