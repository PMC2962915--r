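# Seeded synthetic time-course generation. The generator shares the forward
# model with the fitting code only through the exported model-core functions,
# so noiseless generation followed by estimation is an exact round trip.

#' Experiment design for a protection study
#'
#' Captures the concentration grids and sampling schedule of a study:
#' a DTNB titration (default 50-600 uM, six levels) to establish the
#' baseline parameters of each variant, and protection runs at a fixed
#' working DTNB concentration (default 200 uM) with a graded ligand series.
#' When `time_points` is `NULL`, activity-mode samples are placed evenly
#' over `n_half_lives` half-lives of each course (default 12 points over 3
#' half-lives, which keeps the log-linear fit well conditioned); absorbance
#' traces are sampled every `trace_interval` seconds over the same span.
#'
#' @param dtnb_grid DTNB concentrations for the saturation series, uM.
#' @param coenzyme_grids optional named list mapping coenzyme identifiers to
#'   concentration grids (mM) for protection runs; when omitted, protection
#'   grids default to `{0, 0.25, 0.5, 1, 2, 4} * Kd`.
#' @param fixed_dtnb working DTNB concentration for protection runs, uM.
#' @param time_points explicit sampling times (s), overriding the automatic
#'   schedule; strictly increasing.
#' @param n_points number of activity-mode samples per course.
#' @param n_half_lives span of the automatic schedule, in half-lives.
#' @param trace_interval absorbance sampling interval, s.
#' @param trace_duration absorbance trace duration, s (default: automatic).
#' @param replicates replicate courses per condition.
#' @return an object of class `experiment_design`.
#' @export
experiment_design <- function(dtnb_grid = c(50, 100, 200, 300, 400, 600),
                              coenzyme_grids = NULL,
                              fixed_dtnb = 200,
                              time_points = NULL,
                              n_points = 12L,
                              n_half_lives = 3,
                              trace_interval = 10,
                              trace_duration = NULL,
                              replicates = 1L) {
  stopifnot(all(dtnb_grid >= 0), fixed_dtnb > 0, n_points >= 3,
            n_half_lives > 0, trace_interval > 0, replicates >= 1)
  if (!is.null(time_points)) {
    stopifnot(all(diff(time_points) > 0), all(time_points >= 0))
  }
  if (!is.null(coenzyme_grids)) {
    stopifnot(is.list(coenzyme_grids), !is.null(names(coenzyme_grids)),
              all(vapply(coenzyme_grids, function(g) all(g >= 0), logical(1))))
  }
  structure(list(dtnb_grid = dtnb_grid, coenzyme_grids = coenzyme_grids,
                 fixed_dtnb = fixed_dtnb, time_points = time_points,
                 n_points = as.integer(n_points), n_half_lives = n_half_lives,
                 trace_interval = trace_interval,
                 trace_duration = trace_duration,
                 replicates = as.integer(replicates)),
            class = "experiment_design")
}

#' Measurement-noise specification
#'
#' `"multiplicative_gaussian"` scales each value by `1 + N(0, sigma)` (assay
#' error grows with signal; the activity-mode default at sigma = 0.02);
#' `"additive_gaussian"` adds `N(0, sigma)` (photometric error; the
#' absorbance-mode default at sigma = 0.002 AU); `"none"` forces sigma = 0.
#'
#' @param model noise model.
#' @param sigma noise scale (fraction for multiplicative, AU for additive).
#' @param seed integer seed; series generators derive per-course child seeds
#'   from it so draws are reproducible and insertion-stable.
#' @return an object of class `noise_spec`.
#' @export
noise_spec <- function(model = c("none", "additive_gaussian",
                                 "multiplicative_gaussian"),
                       sigma = 0, seed = NULL) {
  model <- match.arg(model)
  stopifnot(sigma >= 0)
  if (model == "none" && sigma != 0) {
    stop_shprotect("noise model 'none' forces sigma = 0",
                   "shprotect_config_error")
  }
  if (model != "none" && sigma == 0) model <- "none"
  structure(list(model = model, sigma = sigma, seed = seed),
            class = "noise_spec")
}

apply_noise <- function(values, noise, seed) {
  if (noise$model == "none") return(values)
  with_local_seed(seed, {
    eps <- rnorm(length(values), 0, noise$sigma)
    switch(noise$model,
           additive_gaussian = values + eps,
           multiplicative_gaussian = values * (1 + eps))
  })
}

default_times <- function(k, design, mode) {
  if (!is.null(design$time_points)) return(design$time_points)
  stopifnot(k > 0)
  span <- design$n_half_lives * log(2) / k
  if (mode == "activity") {
    seq(0, span, length.out = design$n_points)
  } else {
    dur <- design$trace_duration %||% span
    n <- floor(dur / design$trace_interval)
    if (n < 5) seq(0, dur, length.out = 25L)
    else seq(0, n * design$trace_interval, by = design$trace_interval)
  }
}

new_time_course <- function(times, values, mode, variant, cond,
                            replicate, seed, truth_k) {
  structure(list(times = times, values = values, mode = mode,
                 variant = variant,
                 dtnb_uM = cond$dtnb_M * 1e6,
                 coenzyme = cond$coenzyme,
                 co_mM = cond$co_M * 1e3,
                 replicate = as.integer(replicate),
                 seed = seed, truth_k = truth_k),
            class = "time_course")
}

#' @export
print.time_course <- function(x, ...) {
  cat(sprintf(
    "<time_course> %s | %s | DTNB %g uM | %s %g mM | %d points%s\n",
    x$variant, x$mode, x$dtnb_uM, x$coenzyme, x$co_mM, length(x$times),
    if (!is.null(x$truth_k)) sprintf(" | truth k = %.4g s^-1", x$truth_k)
    else ""))
  invisible(x)
}

#' @export
as.data.frame.time_course <- function(x, ...) {
  data.frame(time_s = x$times, value = x$values, mode = x$mode,
             variant = x$variant, dtnb_uM = x$dtnb_uM,
             coenzyme = x$coenzyme, co_mM = x$co_mM,
             replicate = x$replicate,
             seed = if (is.null(x$seed)) NA_integer_ else x$seed,
             stringsAsFactors = FALSE)
}

#' Generate one synthetic modification time course
#'
#' Evaluates the forward model ([activity_fraction] or [a412_signal]) at the
#' design's sampling times for the rate constant implied by `params`,
#' `binding` and `cond`, then applies the noise model. The generating rate
#' constant is recorded in the `truth_k` field. Identical seeds reproduce
#' identical values bit for bit.
#'
#' @param params an [inactivation_params] object.
#' @param binding a [coenzyme_binding] object, or `NULL` for an unprotected
#'   course.
#' @param cond a [protection_conditions] object.
#' @param design an [experiment_design].
#' @param sig a [signal_model]; absorbance mode requires `sh_conc`.
#' @param noise a [noise_spec].
#' @param variant enzyme identifier carried into the output.
#' @param replicate replicate index carried into the output.
#' @return an object of class `time_course`.
#' @export
generate_timecourse <- function(params, binding = NULL, cond,
                                design = experiment_design(),
                                sig = signal_model(),
                                noise = noise_spec(),
                                variant = "enzyme", replicate = 1L) {
  stopifnot(inherits(cond, "protection_conditions"),
            inherits(design, "experiment_design"),
            inherits(sig, "signal_model"), inherits(noise, "noise_spec"))
  truth_k <- if (is.null(binding)) {
    k_inactivation(params, cond$dtnb_M, unit = "M")
  } else {
    k_protected(params, binding, cond)
  }
  times <- default_times(truth_k, design, sig$mode)
  clean <- if (sig$mode == "activity") {
    activity_fraction(truth_k, times)
  } else {
    a412_signal(truth_k, times, sig)
  }
  values <- apply_noise(clean, noise, noise$seed)
  new_time_course(times, values, sig$mode, variant, cond, replicate,
                  noise$seed, truth_k)
}

series_noise <- function(noise, variant, mode, key) {
  if (noise$model == "none") return(noise)
  noise_spec(noise$model, noise$sigma,
             child_seed(noise$seed, paste(variant, mode, key, sep = "|")))
}

#' Generate a DTNB saturation series
#'
#' One unprotected time course per DTNB level of the design grid. The
#' generating rate constants are monotone nondecreasing in the DTNB
#' concentration.
#'
#' @inheritParams generate_timecourse
#' @return list of `time_course` objects.
#' @export
generate_dtnb_series <- function(params, design = experiment_design(),
                                 sig = signal_model(),
                                 noise = noise_spec(), variant = "enzyme") {
  if (length(design$dtnb_grid) == 0) {
    stop_shprotect("dtnb_grid is empty", "shprotect_config_error")
  }
  out <- list()
  for (d in design$dtnb_grid) {
    for (r in seq_len(design$replicates)) {
      key <- sprintf("dtnb=%g|rep=%d", d, r)
      out[[length(out) + 1L]] <- generate_timecourse(
        params, NULL, protection_conditions(d, 0, "none"),
        design, sig, series_noise(noise, variant, sig$mode, key),
        variant = variant, replicate = r)
    }
  }
  out
}

#' Generate a protection series at fixed DTNB
#'
#' One time course per ligand level, always including the zero-ligand course
#' (so the fitted protection-line intercept can be cross-checked against the
#' unprotected rate). Generating rate constants decrease strictly with
#' ligand concentration for a finite Kd.
#'
#' @inheritParams generate_timecourse
#' @param co_grid ligand concentrations in mM; defaults to the design's grid
#'   for this coenzyme, or `{0, 0.25, 0.5, 1, 2, 4} * Kd`.
#' @return list of `time_course` objects.
#' @export
generate_protection_series <- function(params, binding,
                                       design = experiment_design(),
                                       sig = signal_model(),
                                       noise = noise_spec(),
                                       variant = "enzyme", co_grid = NULL) {
  stopifnot(inherits(binding, "coenzyme_binding"))
  grid <- co_grid %||% design$coenzyme_grids[[binding$coenzyme]]
  if (is.null(grid)) {
    if (is.infinite(binding$Kd_M)) {
      stop_shprotect(
        "a non-binding ligand has no natural grid; supply co_grid",
        "shprotect_config_error")
    }
    grid <- c(0, 0.25, 0.5, 1, 2, 4) * binding$Kd_M * 1e3
  }
  if (length(grid) == 0) {
    stop_shprotect("coenzyme grid is empty", "shprotect_config_error")
  }
  if (!any(grid == 0)) grid <- c(0, grid)
  grid <- sort(unique(grid))
  out <- list()
  for (co in grid) {
    for (r in seq_len(design$replicates)) {
      key <- sprintf("dtnb=%g|%s=%g|rep=%d",
                     design$fixed_dtnb, binding$coenzyme, co, r)
      out[[length(out) + 1L]] <- generate_timecourse(
        params, binding,
        protection_conditions(design$fixed_dtnb, co, binding$coenzyme),
        design, sig, series_noise(noise, variant, sig$mode, key),
        variant = variant, replicate = r)
    }
  }
  out
}

#' Generate a full synthetic study
#'
#' For every variant in the catalog: one DTNB saturation series plus one
#' protection series per listed coenzyme. Deterministic under a fixed master
#' seed; per-series child seeds are derived by stable hashing of the series
#' identity, so adding a series never perturbs the draws of another.
#'
#' @param catalog named list, one entry per variant, each a list with
#'   elements `params` (an [inactivation_params]) and `coenzymes` (a named
#'   list of [coenzyme_binding] objects, possibly empty). See [gdh_catalog].
#' @param design an [experiment_design].
#' @param noise a [noise_spec]; its `seed` acts as the master seed.
#' @param sig a [signal_model].
#' @return an object of class `study`: a list of `time_course` objects with
#'   the catalog attached; convert to a tidy table with `as.data.frame()`.
#' @export
generate_study <- function(catalog, design = experiment_design(),
                           noise = noise_spec(), sig = signal_model()) {
  stopifnot(is.list(catalog), length(catalog) > 0)
  if (is.null(names(catalog)) || anyDuplicated(names(catalog))) {
    stop_shprotect("catalog variant names must be unique and non-empty",
                   "shprotect_config_error")
  }
  courses <- list()
  for (variant in names(catalog)) {
    entry <- catalog[[variant]]
    courses <- c(courses, generate_dtnb_series(
      entry$params, design, sig, noise, variant = variant))
    for (binding in entry$coenzymes) {
      courses <- c(courses, generate_protection_series(
        entry$params, binding, design, sig, noise, variant = variant))
    }
  }
  structure(list(courses = courses, catalog = catalog, design = design),
            class = "study")
}

#' @export
as.data.frame.study <- function(x, ...) {
  do.call(rbind, lapply(x$courses, as.data.frame))
}

#' @export
print.study <- function(x, ...) {
  df <- as.data.frame(x)
  cat(sprintf("<study> %d variants, %d time courses, %d observations\n",
              length(x$catalog), length(x$courses), nrow(df)))
  invisible(x)
}
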