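#' Reference kinetic parameters for clostridial glutamate dehydrogenase
#'
#' The published chemical-modification and coenzyme-binding parameter set for
#' NAD+-dependent glutamate dehydrogenase of *Clostridium symbiosum*:
#' wild-type plus four engineered coenzyme-binding-site variants (F238S,
#' P262S, the F238S/P262S double mutant, and D263K). Each entry carries the
#' covalent rate constant `j` (s^-1) and DTNB dissociation constant `K_DTNB`
#' (uM) governing inactivation by Ellman's reagent, and the dissociation
#' constants (mM) of the binary complexes with NAD+, NADH and NADPH measured
#' by the protection method. Standard errors of the baseline parameters are
#' attached as the `se` element.
#'
#' This catalog is the default ground truth for [generate_study]: a noiseless
#' synthetic study generated from it and pushed through the full pipeline
#' returns exactly these numbers, which is the package's primary
#' self-consistency check.
#'
#' @return named list keyed by variant, each element a list with `params`
#'   (an [inactivation_params]), `se` (list with `j` and `K_DTNB`), and
#'   `coenzymes` (named list of [coenzyme_binding] objects).
#' @examples
#' cat <- gdh_catalog()
#' names(cat)
#' cat[["Wild-type"]]$params
#' @export
gdh_catalog <- function() {
  entry <- function(j, se_j, K, se_K, kd_nad, kd_nadh, kd_nadph) {
    list(params = inactivation_params(j, K),
         se = list(j = se_j, K_DTNB = se_K),
         coenzymes = list(
           `NAD+`  = coenzyme_binding("NAD+",  kd_nad),
           `NADH`  = coenzyme_binding("NADH",  kd_nadh),
           `NADPH` = coenzyme_binding("NADPH", kd_nadph)))
  }
  list(
    `Wild-type`   = entry(3.52e-3, 0.14e-3,  990,  6.8, 0.335, 0.024, 0.023),
    `F238S`       = entry(7.95e-3, 0.22e-3, 1190, 17.5, 6.62,  0.232, 1.30),
    `P262S`       = entry(3.45e-3, 0.17e-3,  758, 23.1, 2.84,  0.052, 0.375),
    `F238S/P262S` = entry(5.28e-3, 0.36e-3,  981, 13.4, 4.30,  0.253, 0.526),
    `D263K`       = entry(2.50e-3, 0.12e-3,  338, 14.5, 2.02,  0.130, 0.228)
  )
}
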