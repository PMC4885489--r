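test_that("zero donor CV and zero noise reproduce the truth exactly", {
  spec <- synthetic_induction_spec(n_donors = 4, cv_Ind_max = 0,
                                   cv_IndC_50 = 0, noise_cv = 0, seed = 2)
  ds <- make_induction_dataset(spec)
  expect_length(ds, 4)
  expect_equal(ds[[1]]$fold_response, ds[[4]]$fold_response)
  expect_length(ds[[1]]$concentrations, 7)
  f <- fit_sigmoid(ds[[1]])
  expect_lt(abs(f$Ind_max - 22.7) / 22.7, 1e-6)
  expect_lt(abs(f$IndC_50 - 0.30) / 0.30, 1e-6)
})

test_that("generators are deterministic under a fixed seed", {
  spec <- synthetic_induction_spec(seed = 9)
  a <- make_induction_dataset(spec)
  b <- make_induction_dataset(spec)
  expect_identical(a[[2]]$fold_response, b[[2]]$fold_response)
  spec2 <- synthetic_induction_spec(seed = 10)
  c2 <- make_induction_dataset(spec2)
  expect_false(isTRUE(all.equal(a[[1]]$fold_response, c2[[1]]$fold_response)))
})

test_that("donor spread emulates the bundled rifampicin activity table", {
  # replicated four-donor experiments: the grand mean of donor-mean
  # parameters stays near the generating truth
  nrep <- 60
  means_im <- means_ic <- numeric(nrep)
  for (i in seq_len(nrep)) {
    spec <- synthetic_induction_spec(seed = 300 + i)
    fits <- lapply(make_induction_dataset(spec), fit_sigmoid)
    s <- summarize_donors(fits)
    means_im[i] <- s$mean_Ind_max
    means_ic[i] <- s$mean_IndC_50
  }
  se_im <- sd(means_im) / sqrt(nrep)
  se_ic <- sd(means_ic) / sqrt(nrep)
  expect_lt(abs(mean(means_im) - 22.7), 2 * se_im + 0.05 * 22.7)
  expect_lt(abs(mean(means_ic) - 0.30), 2 * se_ic + 0.05 * 0.30)
})

test_that("midazolam-like archetype hits its design targets in simulation", {
  vic <- make_compound_profile("midazolam_like")
  s <- simulate_ddi(vic, dose_regimen(vic$name, 15, "oral"),
                    options = fast_opts)
  expect_gte(s$victim$F_G, 0.4)
  expect_lte(s$victim$F_G, 0.6)
  expect_gte(s$victim$fm_CYP3A4, 0.85)
})

test_that("gut-extraction archetypes bracket the F_G range", {
  hi <- make_compound_profile("high_fg_victim")
  lo <- make_compound_profile("low_fg_victim")
  shi <- simulate_ddi(hi, dose_regimen(hi$name, 5, "oral"), options = fast_opts)
  slo <- simulate_ddi(lo, dose_regimen(lo$name, 5, "oral"), options = fast_opts)
  expect_gt(shi$victim$F_G, 0.9)
  expect_lt(slo$victim$F_G, 0.35)
})

test_that("rifampicin-like archetype has fixed clearance and cannot autoinduce", {
  p <- make_compound_profile("rifampicin_like")
  enzymes <- vapply(p$elimination, function(e) toupper(e$enzyme), character(1))
  expect_false("CYP3A4" %in% enzymes)
  expect_false(is.null(p$induction))
})

test_that("autoinduction reverses accumulation on multiple dosing", {
  a <- make_compound_profile("autoinducer")
  s <- simulate_ddi(a, dose_regimen("autoinducer", 300, "oral", n_doses = 8,
                                    interval = 24),
                    options = sim_options(rtol = 1e-6, atol = 1e-7,
                                          horizon = 200))
  conc <- s$out$V.A_sys / (a$Vss * 70)
  tr1 <- conc[which.min(abs(s$out$time - 24))]
  tr7 <- conc[which.min(abs(s$out$time - 192))]
  expect_lt(tr7 / tr1, 1)
  expect_gt(s$victim$enz_H_max, 2)
})

test_that("archetype overrides are validated", {
  p <- make_compound_profile("midazolam_like", overrides = list(fu_gut = 0.5))
  expect_equal(p$fu_gut, 0.5)
  expect_error(make_compound_profile("midazolam_like",
                                     overrides = list(fu_p = 1.2)), "fu_p")
  expect_error(make_compound_profile("midazolam_like",
                                     overrides = list(nonsense = 1)),
               "unknown override")
})

test_that("synthetic study tables carry recoverable ground truth", {
  spec <- synthetic_study_spec(n_studies = 2, noise_cv = 0, seed = 7,
                               perp_days_range = c(5, 6))
  tab <- make_study_table(spec, options = fast_opts)
  expect_length(tab$designs, 2)
  expect_true(all(tab$truth$true_ratio > 1))
  # zero observation noise: evaluating truth-parameter predictions
  # against the generated observations gives GMFE exactly 1
  vic <- make_compound_profile("midazolam_like")
  perp <- set_induction(make_compound_profile("rifampicin_like"),
                        tab$truth$induction)
  pred <- vapply(tab$designs, function(d) {
    d$n_subjects <- 1; d$n_trials <- 1
    pool_ratios(run_study(d, vic, perp, cv = cv_zero, seed = spec$seed,
                          options = fast_opts))$pooled_ratio
  }, numeric(1))
  obs <- vapply(tab$observed, observed_ratio, numeric(1))
  expect_equal(gmfe(pred, obs), 1, tolerance = 1e-6)

  # with noise the observations move off the truth but stay deterministic
  spec2 <- synthetic_study_spec(n_studies = 2, noise_cv = 0.3, seed = 7,
                                perp_days_range = c(5, 6))
  tab2 <- make_study_table(spec2, options = fast_opts)
  obs2 <- vapply(tab2$observed, observed_ratio, numeric(1))
  expect_false(isTRUE(all.equal(obs2, obs)))
  tab3 <- make_study_table(spec2, options = fast_opts)
  expect_equal(vapply(tab3$observed, observed_ratio, numeric(1)), obs2)
})

test_that("misspecified induction biases predictions in the expected direction", {
  spec <- synthetic_study_spec(n_studies = 2, noise_cv = 0, seed = 13,
                               perp_days_range = c(5, 6))
  tab <- make_study_table(spec, options = fast_opts)
  vic <- make_compound_profile("midazolam_like")
  half <- lapply(tab$truth$induction, function(v)
    c(Ind_max = unname(1 + (v[["Ind_max"]] - 1) / 2),
      IndC_50 = unname(v[["IndC_50"]])))
  perp_half <- set_induction(make_compound_profile("rifampicin_like"), half)
  pred <- vapply(tab$designs, function(d) {
    d$n_subjects <- 1; d$n_trials <- 1
    pool_ratios(run_study(d, vic, perp_half, cv = cv_zero, seed = spec$seed,
                          options = fast_opts))$pooled_ratio
  }, numeric(1))
  obs <- vapply(tab$observed, observed_ratio, numeric(1))
  expect_true(all(pred < obs))
})
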