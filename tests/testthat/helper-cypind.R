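# shared fixtures: a variability-free population, fast solver settings,
# and small profile builders used across test files

cv_zero <- population_cv(cv_enz_H = 0, cv_enz_G = 0, cv_clu = 0, cv_ka = 0,
                         cv_vss = 0, cv_qh = 0, bw_cv = 0)

fast_opts <- sim_options(rtol = 1e-6, atol = 1e-7)

# single-pathway i.v. victim with fu_B * CLu_int_H = 100 L/h
wellstirred_victim <- function() {
  compound_profile("ws", MW = 300, fu_p = 1, BP = 1, Vss = 0.7,
                   elimination = list(
                     pathway_clearance("CYP3A4", "liver", CLu_int = 100)))
}

# oral victim with fu_gut * CLu_int_G = Q_gut (F_G = 0.5) and a fixed
# hepatic pathway
half_fg_victim <- function(Q_gut = 18) {
  compound_profile("hf", MW = 300, fu_p = 0.1, BP = 1, fu_gut = 1,
                   Vss = 0.7, ka = 1,
                   elimination = list(
                     pathway_clearance("CYP3A4", "gut", CLu_int = Q_gut),
                     pathway_clearance("other", "liver", CLu_int = 100)))
}

# perpetrator shell with the given site induction parameters, dosed or
# used via clamping
inducer_shell <- function(Ind_max = 16, IndC_50 = 0.32, mbi = NULL) {
  compound_profile("shell", MW = 400, fu_p = 0.5, BP = 1, Vss = 0.7,
                   mbi = mbi,
                   induction = list(liver = c(Ind_max, IndC_50),
                                    gut = c(Ind_max, IndC_50)))
}

noiseless_fit <- function(inducer = "rifampicin", Ind_max = 22.7,
                          IndC_50 = 0.30, model = "three_param") {
  g <- concentration_grid(inducer)
  d <- induction_dataset(inducer, "D1", "activity", g,
                         induction_curve(g, 1, Ind_max, IndC_50, 1))
  fit_sigmoid(d, model)
}
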