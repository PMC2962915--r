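# Closed-form kinetic model for protection of an active-site cysteine
# against chemical modification.
#
# The scheme: the modifier (DTNB) binds the enzyme rapidly and reversibly
# (dissociation constant K_DTNB); the noncovalent complex then reacts in a
# slower first-order covalent step (true rate constant j) to give the
# inactive thionitrobenzoate adduct. A competing ligand ("coenzyme", Kd)
# sequesters free enzyme and so slows the observed inactivation. With both
# binding steps at rapid equilibrium the observed pseudo-first-order rate
# constant is
#
#   k_Co = j [DTNB] / ( K_DTNB (1 + [Co]/Kd) + [DTNB] )
#
# whose reciprocal is affine in [Co]: the basis of the protection plot.

#' Inactivation parameters for one enzyme variant
#'
#' Bundles the two constants of the modification scheme: `j`, the first-order
#' rate constant of the covalent step within the noncovalent enzyme-modifier
#' complex (s^-1), and `K_DTNB`, the dissociation constant of that complex.
#'
#' @param j covalent rate constant, s^-1; must be positive.
#' @param K_DTNB dissociation constant of the enzyme-DTNB complex; positive.
#' @param K_unit unit of `K_DTNB` (default micromolar).
#' @return an object of class `inactivation_params`.
#' @examples
#' inactivation_params(j = 3.52e-3, K_DTNB = 990)
#' @export
inactivation_params <- function(j, K_DTNB, K_unit = "uM") {
  stopifnot(is.numeric(j), length(j) == 1L, is.finite(j), j > 0)
  K_M <- conc_to_molar(K_DTNB, K_unit)
  stopifnot(length(K_M) == 1L, is.finite(K_M), K_M > 0)
  structure(list(j = j, K_DTNB_M = K_M), class = "inactivation_params")
}

#' @export
print.inactivation_params <- function(x, ...) {
  cat(sprintf("<inactivation_params> j = %.4g s^-1, K_DTNB = %.4g uM\n",
              x$j, x$K_DTNB_M * 1e6))
  invisible(x)
}

#' Enzyme-coenzyme binding descriptor
#'
#' @param coenzyme identifier, e.g. `"NAD+"`, `"NADH"`, `"NADPH"`.
#' @param Kd dissociation constant of the binary enzyme-coenzyme complex.
#'   `Inf` is the explicit non-binding sentinel (no protection).
#' @param Kd_unit unit of `Kd` (default millimolar).
#' @return an object of class `coenzyme_binding`.
#' @examples
#' coenzyme_binding("NAD+", 0.335)
#' non_binding("sorbitol")
#' @export
coenzyme_binding <- function(coenzyme, Kd, Kd_unit = "mM") {
  stopifnot(is.character(coenzyme), length(coenzyme) == 1L, nzchar(coenzyme),
            is.numeric(Kd), length(Kd) == 1L, !is.na(Kd), Kd > 0)
  Kd_M <- if (is.infinite(Kd)) Inf else conc_to_molar(Kd, Kd_unit)
  structure(list(coenzyme = coenzyme, Kd_M = Kd_M), class = "coenzyme_binding")
}

#' @rdname coenzyme_binding
#' @export
non_binding <- function(coenzyme = "none") coenzyme_binding(coenzyme, Inf)

is_non_binding <- function(binding) {
  is.null(binding) || is.infinite(binding$Kd_M)
}

#' @export
print.coenzyme_binding <- function(x, ...) {
  if (is.infinite(x$Kd_M)) {
    cat(sprintf("<coenzyme_binding> %s: non-binding\n", x$coenzyme))
  } else {
    cat(sprintf("<coenzyme_binding> %s: Kd = %.4g mM\n",
                x$coenzyme, x$Kd_M * 1e3))
  }
  invisible(x)
}

#' Observation model for a modification time course
#'
#' Two observation modes are supported: `"activity"` (residual catalytic
#' activity fraction from timed assay samples) and `"absorbance"` (continuous
#' A412 trace of released thionitrobenzoate anion, extinction coefficient
#' 13.6 mM^-1 cm^-1).
#'
#' @param mode `"activity"` or `"absorbance"`.
#' @param extinction_coeff molar absorptivity of the TNB anion at 412 nm,
#'   mM^-1 cm^-1.
#' @param path_length optical path length, cm.
#' @param sh_conc concentration of modifiable -SH groups, micromolar;
#'   required for absorbance mode.
#' @return an object of class `signal_model`.
#' @export
signal_model <- function(mode = c("activity", "absorbance"),
                         extinction_coeff = 13.6, path_length = 1,
                         sh_conc = NULL) {
  mode <- match.arg(mode)
  stopifnot(extinction_coeff > 0, path_length > 0)
  if (mode == "absorbance" && (is.null(sh_conc) || !(sh_conc > 0))) {
    stop_shprotect("absorbance mode requires a positive sh_conc (uM)",
                   "shprotect_config_error")
  }
  structure(list(mode = mode, extinction_coeff = extinction_coeff,
                 path_length = path_length, sh_conc_uM = sh_conc),
            class = "signal_model")
}

#' Experimental conditions of one modification reaction
#'
#' @param dtnb_conc modifier concentration (default unit micromolar);
#'   must be positive.
#' @param co_conc protecting-ligand concentration (default unit millimolar);
#'   non-negative.
#' @param coenzyme ligand identifier; `"none"` for unprotected runs.
#' @param dtnb_unit,co_unit units of the two concentrations.
#' @return an object of class `protection_conditions`.
#' @export
protection_conditions <- function(dtnb_conc, co_conc = 0, coenzyme = "none",
                                  dtnb_unit = "uM", co_unit = "mM") {
  dtnb_M <- conc_to_molar(dtnb_conc, dtnb_unit)
  co_M <- conc_to_molar(co_conc, co_unit)
  stopifnot(length(dtnb_M) == 1L, length(co_M) == 1L)
  if (!is.finite(dtnb_M) || dtnb_M <= 0) {
    stop_shprotect("dtnb_conc must be positive", "shprotect_domain_error")
  }
  if (co_M < 0) stop_shprotect("co_conc must be >= 0", "shprotect_domain_error")
  structure(list(dtnb_M = dtnb_M, co_M = co_M, coenzyme = coenzyme),
            class = "protection_conditions")
}

#' Pseudo-first-order inactivation rate constant (no protecting ligand)
#'
#' Saturation law for the two-step modification scheme:
#' `k = j [DTNB] / (K_DTNB + [DTNB])`. Monotone nondecreasing in the modifier
#' concentration, with asymptote `j`.
#'
#' @param params an [inactivation_params] object.
#' @param dtnb_conc modifier concentration, non-negative.
#' @param unit unit of `dtnb_conc` (default micromolar).
#' @return rate constant in s^-1.
#' @examples
#' wt <- inactivation_params(3.52e-3, 990)
#' k_inactivation(wt, 200)  # 5.916e-4 s^-1
#' @export
k_inactivation <- function(params, dtnb_conc, unit = "uM") {
  stopifnot(inherits(params, "inactivation_params"))
  D <- conc_to_molar(dtnb_conc, unit)
  if (any(D < 0)) {
    stop_shprotect("dtnb_conc must be >= 0", "shprotect_domain_error")
  }
  params$j * D / (params$K_DTNB_M + D)
}

#' Inactivation rate constant in the presence of a protecting ligand
#'
#' Three-species competition: the enzyme distributes between free enzyme,
#' enzyme-ligand and enzyme-DTNB complexes, and only the last reacts.
#' `k_Co = j [DTNB] / (K_DTNB (1 + [Co]/Kd) + [DTNB])`. At `[Co] = 0` this
#' reduces to [k_inactivation]; a non-binding ligand (`Kd = Inf`) leaves the
#' rate unchanged at any concentration.
#'
#' @param params an [inactivation_params] object.
#' @param binding a [coenzyme_binding] object, or `NULL` for no ligand.
#' @param cond a [protection_conditions] object.
#' @return rate constant in s^-1.
#' @examples
#' wt <- inactivation_params(3.52e-3, 990)
#' nad <- coenzyme_binding("NAD+", 0.335)
#' k_protected(wt, nad, protection_conditions(200, 0.335, "NAD+"))
#' @export
k_protected <- function(params, binding, cond) {
  stopifnot(inherits(params, "inactivation_params"),
            inherits(cond, "protection_conditions"))
  occupancy <- if (is_non_binding(binding)) 0 else cond$co_M / binding$Kd_M
  params$j * cond$dtnb_M /
    (params$K_DTNB_M * (1 + occupancy) + cond$dtnb_M)
}

#' Maximal (unprotected) rate constant at the working modifier concentration
#'
#' The zero-ligand limit of [k_protected]: the saturation law evaluated at
#' the working DTNB concentration. This is the quantity whose reciprocal is
#' the ordinate intercept of the protection line.
#'
#' @inheritParams k_inactivation
#' @return rate constant in s^-1.
#' @export
k_max <- function(params, dtnb_conc, unit = "uM") {
  D <- conc_to_molar(dtnb_conc, unit)
  if (any(!is.finite(D) & D > 0)) return(params$j)  # dtnb -> Inf asymptote
  if (any(D <= 0)) {
    stop_shprotect("dtnb_conc must be positive", "shprotect_domain_error")
  }
  k_inactivation(params, dtnb_conc, unit)
}

#' Slope and intercept of the protection line
#'
#' The reciprocal of [k_protected] is affine in the ligand concentration:
#' `1/k_Co = slope * [Co] + intercept` with
#' `slope = (1/j) (K_DTNB/[DTNB]) (1/Kd)` and `intercept = 1/k_max`.
#' Slope is returned per millimolar so that it multiplies concentrations
#' expressed in mM; a non-binding ligand gives an exactly zero slope.
#'
#' @inheritParams k_protected
#' @param dtnb_conc working modifier concentration, positive.
#' @param unit unit of `dtnb_conc`.
#' @return list with elements `slope` (s mM^-1) and `intercept` (s).
#' @export
protection_line <- function(params, binding, dtnb_conc, unit = "uM") {
  stopifnot(inherits(params, "inactivation_params"))
  D <- conc_to_molar(dtnb_conc, unit)
  if (!is.finite(D) || D <= 0) {
    stop_shprotect("dtnb_conc must be positive", "shprotect_domain_error")
  }
  intercept <- 1 / (params$j * D / (params$K_DTNB_M + D))
  slope_per_M <- if (is_non_binding(binding)) {
    0
  } else {
    (1 / params$j) * (params$K_DTNB_M / D) * (1 / binding$Kd_M)
  }
  list(slope = slope_per_M * 1e-3, intercept = intercept)
}

#' Residual activity fraction of an exponentially inactivating enzyme
#'
#' @param k pseudo-first-order rate constant, s^-1 (non-negative).
#' @param t time(s), s (non-negative); vectorised.
#' @return fraction(s) in (0, 1].
#' @export
activity_fraction <- function(k, t) {
  stopifnot(is.numeric(k), length(k) == 1L, is.numeric(t))
  if (k < 0) stop_shprotect("k must be >= 0", "shprotect_domain_error")
  if (any(t < 0)) stop_shprotect("t must be >= 0", "shprotect_domain_error")
  exp(-k * t)
}

#' A412 trace of thionitrobenzoate release
#'
#' Beer-Lambert signal of the chromophoric TNB anion released one-for-one
#' with modified -SH groups: `A(t) = eps * l * [SH]0 * (1 - exp(-k t))`,
#' rising monotonically to the plateau `eps * l * [SH]0`.
#'
#' @inheritParams activity_fraction
#' @param sig a [signal_model] in absorbance mode (supplies the extinction
#'   coefficient, path length and total -SH concentration).
#' @return absorbance value(s), AU.
#' @export
a412_signal <- function(k, t, sig) {
  stopifnot(inherits(sig, "signal_model"))
  if (sig$mode != "absorbance" || is.null(sig$sh_conc_uM)) {
    stop_shprotect("a412_signal requires an absorbance-mode signal_model",
                   "shprotect_config_error")
  }
  plateau <- sig$extinction_coeff * sig$path_length * sig$sh_conc_uM / 1e3
  plateau * (1 - activity_fraction(k, t))
}

#' Concentration of released TNB anion from an absorbance change
#'
#' Inverts Beer-Lambert: `[TNB] = 1000 * dA / (eps * l)` micromolar. When a
#' subunit concentration is supplied the modification stoichiometry
#' (-SH modified per subunit) is reported as well.
#'
#' @param delta_a412 absorbance change at 412 nm, non-negative.
#' @param sig a [signal_model] (any mode; supplies eps and path length).
#' @param subunit_conc optional enzyme subunit concentration, micromolar.
#' @return released TNB in micromolar, or (with `subunit_conc`) a list with
#'   elements `tnb_uM` and `stoichiometry`.
#' @export
tnb_released <- function(delta_a412, sig = signal_model(), subunit_conc = NULL) {
  stopifnot(is.numeric(delta_a412))
  if (any(delta_a412 < 0)) {
    stop_shprotect("delta_a412 must be >= 0", "shprotect_domain_error")
  }
  tnb_uM <- 1e3 * delta_a412 / (sig$extinction_coeff * sig$path_length)
  if (is.null(subunit_conc)) return(tnb_uM)
  stopifnot(subunit_conc > 0)
  list(tnb_uM = tnb_uM, stoichiometry = tnb_uM / subunit_conc)
}
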