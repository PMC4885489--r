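test_that("noiseless sigmoid data are recovered to machine-level accuracy", {
  for (case in list(c(22.7, 0.30), c(16.6, 59.1))) {
    ind <- if (case[2] < 1) "rifampicin" else "carbamazepine"
    f <- noiseless_fit(ind, case[1], case[2])
    expect_true(f$converged)
    expect_lt(abs(f$Ind_max - case[1]) / case[1], 1e-6)
    expect_lt(abs(f$IndC_50 - case[2]) / case[2], 1e-6)
    expect_lt(abs(f$baseline - 1), 1e-6)
  }
})

test_that("three- and four-parameter fits agree on hill = 1 data", {
  f3 <- noiseless_fit(model = "three_param")
  f4 <- noiseless_fit(model = "four_param")
  expect_lt(abs(f4$Ind_max - f3$Ind_max) / f3$Ind_max, 1e-4)
  expect_lt(abs(f4$IndC_50 - f3$IndC_50) / f3$IndC_50, 1e-4)
  expect_lt(abs(f4$hill - 1), 1e-3)
})

test_that("flat (no induction) data give Ind_max near 1 and are flagged", {
  g <- concentration_grid("rifampicin")
  d <- induction_dataset("x", "D1", "activity", g, rep(1, length(g)))
  f <- fit_sigmoid(d)
  expect_lt(abs(f$Ind_max - 1), 0.05)
  expect_true("ill_conditioned" %in% f$flags)
  expect_true(is.infinite(f$se_IndC_50) || f$se_IndC_50 > f$IndC_50)
})

test_that("fits with IndC_50 above the tested range are flagged extrapolated", {
  g <- concentration_grid("rifampicin") # top 30 uM
  d <- induction_dataset("x", "D1", "activity", g,
                         induction_curve(g, 1, 20, 200, 1))
  f <- fit_sigmoid(d)
  expect_true("extrapolated" %in% f$flags)
})

test_that("dataset invariants and fit preconditions are enforced", {
  expect_error(induction_dataset("x", "D1", "activity", c(1, 2, -1), c(1, 2, 3)),
               "positive")
  expect_error(induction_dataset("x", "D1", "activity", c(1, 1, 2), c(1, 2, 3)),
               "unique")
  expect_error(induction_dataset("x", "D1", "activity", c(1, 2), c(1, -2)),
               "positive")
  d <- induction_dataset("x", "D1", "activity", c(1, 3, 10), c(1, 2, 3))
  expect_error(fit_sigmoid(d), "4 distinct")
  d4 <- induction_dataset("x", "D1", "activity", c(1, 3, 10, 30), c(1, 2, 3, 4))
  expect_error(fit_sigmoid(d4, "four_param"), "fewer")
})

test_that("predict_fold matches analytic values and is monotone/bounded", {
  f <- structure(list(baseline = 1, Ind_max = 16, IndC_50 = 0.32, hill = 1),
                 class = "induction_fit")
  expect_equal(predict_fold(f, 0.32), 8.5)
  expect_equal(predict_fold(f, 0), 1)
  f2 <- structure(list(baseline = 1, Ind_max = 8, IndC_50 = 0.32, hill = 1),
                  class = "induction_fit")
  expect_equal(predict_fold(f2, 3.2), 1 + 7 * (3.2 / 3.52), tolerance = 1e-12)
  expect_error(predict_fold(f, -1), "non-negative")
  set.seed(11)
  for (i in 1:20) {
    fr <- structure(list(baseline = runif(1, 0.5, 2),
                         Ind_max = runif(1, 1, 40),
                         IndC_50 = 10^runif(1, -2, 3),
                         hill = runif(1, 0.5, 3)),
                    class = "induction_fit")
    conc <- sort(10^runif(30, -3, 4))
    y <- predict_fold(fr, conc)
    expect_true(all(diff(y) >= -1e-12))
    expect_true(all(y >= min(fr$baseline, fr$Ind_max) - 1e-9 &
                    y <= max(fr$baseline, fr$Ind_max) + 1e-9))
  }
})

test_that("donor summary reproduces hand-computed mean and SD", {
  fits <- lapply(c(15, 20, 25, 30), function(im)
    structure(list(Ind_max = im, IndC_50 = 1, endpoint = "activity",
                   inducer = "x", converged = TRUE),
              class = "induction_fit"))
  s <- summarize_donors(fits)
  expect_equal(s$mean_Ind_max, 22.5)
  expect_equal(s$sd_Ind_max, sqrt(125 / 3), tolerance = 1e-12)
  expect_equal(s$n_donors, 4L)

  s1 <- summarize_donors(fits[1])
  expect_equal(s1$mean_Ind_max, 15)
  expect_true(is.na(s1$sd_Ind_max))

  bad <- fits
  bad[[2]]$endpoint <- "mRNA"
  expect_error(summarize_donors(bad), "mixed endpoints")
  expect_error(summarize_donors(list()), "empty")
  failed <- fits
  failed[[3]]$converged <- FALSE
  expect_warning(s2 <- summarize_donors(failed), "non-converged")
  expect_equal(s2$n_donors, 3L)
})

test_that("seeded Monte-Carlo recovery under 15% noise has small median bias", {
  truth <- c(16.6, 59.1)
  nrep <- 150
  im <- ic <- numeric(nrep)
  for (i in seq_len(nrep)) {
    spec <- synthetic_induction_spec(
      "carbamazepine", "activity", Ind_max = truth[1], IndC_50 = truth[2],
      n_donors = 1, cv_Ind_max = 0, cv_IndC_50 = 0, noise_cv = 0.15,
      seed = 1000 + i)
    f <- fit_sigmoid(make_induction_dataset(spec)[[1]])
    im[i] <- f$Ind_max; ic[i] <- f$IndC_50
  }
  expect_lt(abs(median(im) / truth[1] - 1), 0.10)
  expect_lt(abs(median(ic) / truth[2] - 1), 0.25)
})

test_that("Ind_max bias vanishes as noise goes to zero", {
  bias <- sapply(c(0.15, 0.05, 0.01), function(cv) {
    est <- sapply(1:40, function(i) {
      spec <- synthetic_induction_spec(
        n_donors = 1, cv_Ind_max = 0, cv_IndC_50 = 0, noise_cv = cv,
        seed = 5000 + i)
      fit_sigmoid(make_induction_dataset(spec)[[1]])$Ind_max
    })
    abs(mean(est) / 22.7 - 1)
  })
  expect_lt(bias[3], 0.005)
  expect_lt(bias[3], bias[1] + 1e-9)
})
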