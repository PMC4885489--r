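test_that("enzyme derivative is zero at baseline and at the analytic steady state", {
  st <- list(Enz_act_H = 1, Enz_act_G = 1, kdeg_H = 0.0193, kdeg_G = 0.03)
  d0 <- enzyme_rhs(st, 0, 0, list(liver = c(16, 0.32), gut = c(16, 0.32)))
  expect_equal(unname(d0), c(0, 0))

  # constant I = IndC_50, Ind_max 16 -> steady state fold 8.5
  st85 <- list(Enz_act_H = 8.5, Enz_act_G = 8.5, kdeg_H = 0.0193, kdeg_G = 0.03)
  dss <- enzyme_rhs(st85, 0.32, 0.32, list(liver = c(16, 0.32), gut = c(16, 0.32)))
  expect_equal(unname(dss), c(0, 0), tolerance = 1e-12)

  expect_error(enzyme_rhs(st, -1, 0, list(liver = c(16, 0.32))), ">= 0")
})

test_that("enzyme relaxation follows the scalar linear-ODE closed form", {
  # I = 3.2 uM, Ind_max 8, IndC_50 0.32:
  # Enz(t) = 7.364 - 6.364 exp(-kdeg t); independent integration of the R
  # right-hand side at tight tolerance, evaluated at t = 1/kdeg
  kdeg <- 0.04
  ind <- list(liver = c(8, 0.32), gut = c(8, 0.32))
  rhs <- function(t, y, p) {
    d <- enzyme_rhs(list(Enz_act_H = y[1], Enz_act_G = y[2],
                         kdeg_H = kdeg, kdeg_G = kdeg), 3.2, 3.2, ind)
    list(unname(d))
  }
  tt <- c(0, 1 / kdeg)
  num <- deSolve::ode(c(1, 1), tt, rhs, NULL, rtol = 1e-12, atol = 1e-14)
  ss <- 1 + 7 * 3.2 / 3.52
  closed <- ss - (ss - 1) * exp(-kdeg * tt[2])
  expect_equal(unname(num[2, 2]), closed, tolerance = 1e-9)
  expect_equal(ss, 7.363636, tolerance = 1e-6)

  # the compiled core reproduces the same trajectory
  vic <- half_fg_victim()
  perp <- inducer_shell(8, 0.32)
  s <- simulate_ddi(vic, dose_regimen("hf", 1, "oral", start_time = 90),
                    perpetrator = perp,
                    clamp = list(I_liver_u = 3.2, I_gut_u = 3.2,
                                 equilibrate = FALSE),
                    enzyme = enzyme_settings(kdeg_H = kdeg, kdeg_G = kdeg),
                    options = sim_options(rtol = 1e-10, atol = 1e-12,
                                          horizon = 120, out_dt = 0.25))
  at <- which(abs(s$out$time - 1 / kdeg) < 1e-9)[1]
  expect_equal(s$out$EnzH[at], closed, tolerance = 1e-7)
})

test_that("time to enzyme steady state scales as 1/kdeg with unchanged plateau", {
  ind <- list(liver = c(8, 0.32), gut = c(8, 0.32))
  vic <- half_fg_victim()
  perp <- inducer_shell(8, 0.32)
  t90 <- sapply(c(0.03, 0.015), function(kdeg) {
    s <- simulate_ddi(vic, dose_regimen("hf", 1, "oral", start_time = 750),
                      perpetrator = perp,
                      clamp = list(I_liver_u = 3.2, I_gut_u = 3.2,
                                   equilibrate = FALSE),
                      enzyme = enzyme_settings(kdeg_H = kdeg, kdeg_G = kdeg),
                      options = sim_options(horizon = 800, out_dt = 0.25))
    ss <- 1 + 7 * 3.2 / 3.52
    expect_equal(max(s$out$EnzH), ss, tolerance = 1e-3)
    s$out$time[which(s$out$EnzH >= 1 + 0.9 * (ss - 1))[1]]
  })
  expect_equal(t90[2] / t90[1], 2, tolerance = 0.02)
})

test_that("clearance terms combine pathways, enzyme fold and inhibition", {
  vic <- compound_profile("v", MW = 300, fu_p = 0.1, BP = 1, Vss = 0.7,
                          elimination = list(
                            pathway_clearance("CYP3A4", "liver", CLu_int = 100),
                            pathway_clearance("other", "liver", CLu_int = 50)))
  base <- clearance_terms(vic)
  expect_equal(base$CLu_int_H, 150)
  expect_equal(base$fm_CYP3A4_H, 100 / 150)

  tripled <- clearance_terms(vic, enzymes = c(liver = 3, gut = 1))
  expect_equal(tripled$CLu_int_H, 350)

  doubled <- clearance_terms(vic, enzymes = c(liver = 2, gut = 1))
  expect_equal(doubled$CLuH_3A4, 2 * base$CLuH_3A4)

  inh <- compound_profile("i", MW = 300, fu_p = 0.1, BP = 1, Vss = 0.7,
                          inhibition = c(CYP3A4 = 1))
  ct <- clearance_terms(vic, I_liver_u = 1, perpetrator = inh)
  expect_equal(ct$CLuH_3A4, 50) # halved by 1 + I/Ki = 2
  expect_equal(ct$CLuH_other, 50)

  expect_error(pathway_clearance("CYP9Z9", "liver", CLu_int = 1),
               "unknown enzyme")
})

test_that("Michaelis-Menten pathways reduce to Vmax/Km at low substrate", {
  vic <- compound_profile("v", MW = 300, fu_p = 0.1, BP = 1, Vss = 0.7,
                          elimination = list(
                            pathway_clearance("CYP3A4", "liver",
                                              Vmax = 30, Km_u = 5)))
  lowS <- clearance_terms(vic)
  expect_equal(lowS$CLu_int_H, 30 * 1000 / (5 * 300), tolerance = 1e-12)
  highS <- clearance_terms(vic, S_liver_u = 5)
  expect_equal(highS$CLu_int_H, lowS$CLu_int_H / 2, tolerance = 1e-12)
})

test_that("i.v. AUC equals Dose/CL for a linear one-compartment setup", {
  v <- compound_profile("t", MW = 300, fu_p = 1, BP = 1, Vss = 50 / 70,
                        CL_renal = 10)
  s <- simulate_ddi(v, dose_regimen("t", 1, "iv_bolus"))
  expect_equal(s$victim$AUC_0_inf, 0.1, tolerance = 1e-3)
})

test_that("hepatic extraction matches the well-stirred closed form", {
  v <- wellstirred_victim() # fu_B * CLu = 100, Q_h = 90
  s <- simulate_ddi(v, dose_regimen("ws", 1, "iv_bolus"))
  expect_equal(s$victim$F_H, 90 / 190, tolerance = 1e-9)
  cl_sim <- 1 / s$victim$AUC_0_inf
  expect_equal(cl_sim, 90 * 100 / 190, tolerance = 0.01)
})

test_that("gut extraction matches the closed form at its midpoint", {
  v <- half_fg_victim() # fu_gut * CLu_G = Q_gut
  s <- simulate_ddi(v, dose_regimen("hf", 10, "oral"))
  expect_equal(s$victim$F_G, 0.5, tolerance = 1e-6)
})

test_that("trapezoid metrics match analytic profiles", {
  m <- extract_metrics(seq(0, 10, 0.5), rep(1, 21))
  expect_equal(m$AUC_0_t, 10)
  expect_true(m$flagged) # no terminal decline identifiable

  tt <- seq(0, 24, 0.25)
  me <- extract_metrics(tt, 2 * exp(-0.2 * tt))
  expect_equal(me$AUC_0_inf, 10, tolerance = 0.005)
  expect_equal(me$lambda_z, 0.2, tolerance = 1e-6)
  expect_equal(me$C_max, 2)
})

test_that("fm_CYP3A4 from flux integrals matches the intrinsic-clearance split", {
  vic <- compound_profile("v", MW = 300, fu_p = 0.1, BP = 1, Vss = 0.7,
                          elimination = list(
                            pathway_clearance("CYP3A4", "liver", CLu_int = 100),
                            pathway_clearance("other", "liver", CLu_int = 50)))
  s <- simulate_ddi(vic, dose_regimen("v", 5, "iv_bolus"))
  expect_equal(s$victim$fm_CYP3A4, 2 / 3, tolerance = 1e-6)
})

test_that("co-dosing a non-inducing, non-inhibiting perpetrator leaves the victim AUC unchanged", {
  vic <- victim_profile("midazolam")
  inert <- compound_profile("inert", MW = 400, fu_p = 0.5, BP = 1, Vss = 0.7,
                            elimination = list(
                              pathway_clearance("other", "liver", CLu_int = 50)))
  a <- simulate_ddi(vic, dose_regimen("midazolam", 15, "oral"),
                    options = fast_opts)
  b <- simulate_ddi(vic, list(dose_regimen("inert", 600, "oral", n_doses = 5),
                              dose_regimen("midazolam", 15, "oral",
                                           start_time = 96)),
                    perpetrator = inert, options = fast_opts)
  expect_equal(b$victim$AUC_0_inf, a$victim$AUC_0_inf, tolerance = 1e-4)
})

test_that("enzyme trajectories stay within [1, Ind_max] under pure induction", {
  vic <- victim_profile("midazolam")
  rif <- perpetrator_profile("rifampicin", model = "model_C")
  s <- simulate_ddi(vic, list(dose_regimen("rifampicin", 600, "oral", n_doses = 7),
                              dose_regimen("midazolam", 15, "oral",
                                           start_time = 160)),
                    perpetrator = rif, options = fast_opts)
  expect_true(all(s$out$EnzH >= 1 - 1e-6))
  expect_true(all(s$out$EnzG >= 1 - 1e-6))
  expect_true(all(s$out$EnzH <= 16 + 1e-6))
  expect_true(all(s$out$EnzG <= 16 + 1e-6))
})

test_that("mass balance: cumulative absorption never exceeds Fa * dose", {
  vic <- victim_profile("midazolam")
  s <- simulate_ddi(vic, dose_regimen("midazolam", 15, "oral"),
                    options = fast_opts)
  expect_true(all(s$out$V.cum_abs <= 15 * vic$Fa + 1e-6))
  expect_equal(max(s$out$V.cum_abs), 15 * vic$Fa, tolerance = 1e-3)
})

test_that("oral induction ratio is at least the i.v. ratio", {
  vic <- victim_profile("midazolam")
  rif <- perpetrator_profile("rifampicin", model = "model_A")
  ratio_for <- function(route) {
    ctl <- simulate_ddi(vic, dose_regimen("midazolam", 5, route),
                        options = fast_opts)
    ind <- simulate_ddi(vic, list(dose_regimen("rifampicin", 600, "oral",
                                               n_doses = 5),
                                  dose_regimen("midazolam", 5, route,
                                               start_time = 113)),
                        perpetrator = rif, options = fast_opts)
    ctl$victim$AUC_0_inf / ind$victim$AUC_0_inf
  }
  r_oral <- ratio_for("oral")
  r_iv <- ratio_for("iv_bolus")
  expect_gt(r_oral, r_iv)
  expect_gt(r_iv, 1)
})

test_that("mechanism-based inactivation lowers the clamped enzyme plateau", {
  vic <- half_fg_victim()
  kdeg <- 0.03
  mbi <- list(K_I = 1, k_inact = 0.05)
  perp <- inducer_shell(8, 0.32, mbi = mbi)
  Iu <- 2
  s <- simulate_ddi(vic, dose_regimen("hf", 1, "oral", start_time = 900),
                    perpetrator = perp,
                    clamp = list(I_liver_u = Iu, I_gut_u = Iu,
                                 equilibrate = FALSE),
                    enzyme = enzyme_settings(kdeg_H = kdeg, kdeg_G = kdeg),
                    options = sim_options(horizon = 1000, rtol = 1e-8))
  stim <- 1 + 7 * Iu / (0.32 + Iu)
  ss <- kdeg * stim / (kdeg + mbi$k_inact * Iu / (mbi$K_I + Iu))
  expect_equal(s$out$EnzH[nrow(s$out)], ss, tolerance = 1e-4)
  expect_lt(ss, stim)
})

test_that("regimen and profile validation raise errors", {
  expect_error(dose_regimen("x", -1, "oral"), "dose")
  expect_error(compound_profile("x", MW = 300, fu_p = 1.2, Vss = 1), "fu_p")
  expect_error(compound_profile("x", MW = 300, fu_p = 0.5, Vss = -1), "Vss")
  expect_error(system_parameters(Q_pv = 100, Q_h = 90), "Q_pv")
  vic <- wellstirred_victim()
  expect_error(simulate_ddi(vic, dose_regimen("nomatch", 1, "iv_bolus")),
               "matches no simulated profile")
})
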