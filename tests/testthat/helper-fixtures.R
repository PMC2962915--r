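# Shared fixtures: the reference parameter set and small builders.

wt_params <- function() inactivation_params(3.52e-3, 990)
f238s_params <- function() inactivation_params(7.95e-3, 1190)
d263k_params <- function() inactivation_params(2.50e-3, 338)

wt_nad <- function() coenzyme_binding("NAD+", 0.335)
wt_nadph <- function() coenzyme_binding("NADPH", 0.023)
f238s_nadph <- function() coenzyme_binding("NADPH", 1.30)

abs_sig <- function(sh_uM = 2) {
  signal_model("absorbance", sh_conc = sh_uM)
}

# A rates table built directly from the forward model (bypassing the
# time-course stage) for stage-2-only tests.
forward_rates <- function(params, dtnb_grid, variant = "enzyme") {
  data.frame(variant = variant, mode = "activity", dtnb_uM = dtnb_grid,
             coenzyme = "none", co_mM = 0, replicate = 1L,
             k_s = k_inactivation(params, dtnb_grid), se_k = 0,
             stringsAsFactors = FALSE)
}

forward_protection_rates <- function(params, binding, co_grid, dtnb = 200,
                                     variant = "enzyme") {
  k <- vapply(co_grid, function(co) {
    k_protected(params, binding,
                protection_conditions(dtnb, co, binding$coenzyme))
  }, numeric(1))
  data.frame(variant = variant, mode = "activity", dtnb_uM = dtnb,
             coenzyme = binding$coenzyme, co_mM = co_grid, replicate = 1L,
             k_s = k, se_k = 0, stringsAsFactors = FALSE)
}
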