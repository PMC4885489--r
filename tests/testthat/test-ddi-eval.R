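test_that("reciprocal ratios reproduce printed worked examples", {
  expect_equal(round(reciprocal_ratio(118, 52.8), 2), 2.23)
  expect_equal(round(reciprocal_ratio(170, 7.00), 1), 24.3)
  expect_equal(reciprocal_ratio(42, 42), 1)
  expect_error(reciprocal_ratio(-1, 2), "> 0")
  expect_error(reciprocal_ratio(1, 0), "> 0")
})

test_that("GMFE matches hand computations and is 1 iff perfect", {
  expect_equal(gmfe(c(2, 3, 10), c(2, 3, 10)), 1)
  expect_equal(gmfe(c(2, 1), c(1, 2)), 2)
  expect_equal(gmfe(c(3, 1, 1), c(1, 1, 3)), 3^(2 / 3), tolerance = 1e-12)
  expect_equal(gmfe(c(3, 1, 1), c(1, 1, 3)), 2.080, tolerance = 1e-3)
  expect_gt(gmfe(c(1.01), c(1)), 1)
  expect_error(gmfe(numeric(0), numeric(0)), "empty")
  expect_error(gmfe(c(1, -2), c(1, 1)), "> 0")
})

test_that("GMFE is swap- and scale-invariant; RMSE is only swap-invariant", {
  set.seed(7)
  for (i in 1:10) {
    p <- exp(rnorm(5)); o <- exp(rnorm(5))
    expect_equal(gmfe(p, o), gmfe(o, p), tolerance = 1e-12)
    expect_equal(rmse(p, o), rmse(o, p), tolerance = 1e-12)
    # fold errors ignore the ratio scale; absolute errors do not
    expect_equal(gmfe(p, o), gmfe(1 / p, 1 / o), tolerance = 1e-12)
  }
  expect_false(isTRUE(all.equal(rmse(c(4, 2), c(2, 1)),
                                rmse(1 / c(4, 2), 1 / c(2, 1)))))
  expect_equal(rmse(c(3), c(1)), 2)
  expect_equal(rmse(c(2, 4), c(1, 1)), sqrt(5), tolerance = 1e-12)
  expect_equal(rmse(c(1, 2), c(1, 2)), 0)
})

test_that("acceptance limits follow the observation-scaled formula", {
  l1 <- acceptance_limits(1, delta = 1)
  expect_equal(c(l1$lower, l1$upper), c(1, 1))
  l2 <- acceptance_limits(2, delta = 1)
  expect_equal(l2$lower, 4 / 3, tolerance = 1e-12)
  expect_equal(l2$upper, 3, tolerance = 1e-12)
  lbig <- acceptance_limits(1e6, delta = 1)
  expect_equal(lbig$upper / 1e6, 2, tolerance = 1e-3)
  expect_error(acceptance_limits(2, delta = 0.5), "delta")
  # ratios below 1 are transformed through the reciprocal
  lr <- acceptance_limits(0.5, delta = 1)
  expect_equal(lr$lower, 1 / 3, tolerance = 1e-12)
  expect_equal(lr$upper, 3 / 4, tolerance = 1e-12)
})

test_that("limits at delta 1.25 are never wider than the two-fold window", {
  R <- c(1, 1.2, 1.5, 2, 3, 5, 10, 25, 64)
  lim <- acceptance_limits(R, delta = 1.25)
  expect_true(all(lim$lower >= R / 2 - 1e-12))
  expect_true(all(lim$upper <= R * 2 + 1e-12))
  expect_true(all(within_limits(R, R, delta = 1.25)))
})

test_that("unweighted geometric mean reproduces the i.v. MDZ observed value", {
  iv_mdz <- c(1.53, 1.92, 2.23, 2.08, 1.73, 2.64)
  expect_equal(round(meta_geomean(iv_mdz), 2), 1.99)
  expect_equal(meta_geomean(c(1, 4)), 2)
  expect_equal(meta_geomean(rep(3.3, 5)), 3.3)
  expect_equal(meta_geomean(c(1, 4), weights = c(1, 0)), 1)
  expect_error(meta_geomean(numeric(0)), "empty")
})

test_that("bundled study tables have the documented shape", {
  rif <- ddi_study_table("rifampicin")
  oth <- ddi_study_table("other")
  expect_equal(nrow(rif), 29)
  expect_equal(nrow(oth), 6)
  expect_equal(sum(rif$route != "oral"), 10)
  expect_equal(sum(rif$route == "oral"), 19)
  expect_equal(sum(rif$victim == "midazolam" & rif$route != "oral"), 6)
  expect_equal(sum(rif$victim == "midazolam" & rif$route == "oral"), 11)
  expect_equal(nrow(ddi_study_table("all")), 35)
})

test_that("stored AUC columns round-trip to the printed ratios", {
  tab <- ddi_study_table("all")
  recomputed <- reciprocal_ratio(tab$auc_control, tab$auc_induced)
  printed <- as.numeric(tab$ratio_printed)
  decimals <- vapply(strsplit(tab$ratio_printed, ".", fixed = TRUE),
                     function(p) if (length(p) > 1) nchar(p[2]) else 0L,
                     integer(1))
  tol <- 10^(-decimals) # one unit in the last printed digit
  ok <- abs(recomputed - printed) <= tol + 1e-12
  flagged <- tab$dose_escalated | tab$ratio_mismatch
  expect_true(all(ok[!flagged]))
  expect_gte(sum(ok), 31)
  expect_equal(sum(flagged), 4)
  expect_true(all(!ok[tab$dose_escalated])) # clearance-derived ratios
})

test_that("degenerate accuracy summary: perfect predictions score perfectly", {
  obs <- c(1.5, 2.2, 8, 24)
  s <- accuracy_summary(obs, obs)
  expect_equal(s$GMFE, 1)
  expect_equal(s$RMSE, 0)
  expect_equal(s$pct_within_limits, 100)
})

test_that("observed_study keeps printed ratios authoritative", {
  o <- observed_study("s", "midazolam", "oral", 12, 27.1, 19.9,
                      ratio_printed = "17.0", dose_escalated = TRUE)
  expect_equal(observed_ratio(o), 17.0)
  expect_equal(o$ratio_recip, 27.1 / 19.9, tolerance = 1e-12)
  o2 <- observed_study("s2", "midazolam", "oral", 10, 170, 7)
  expect_equal(observed_ratio(o2), 170 / 7)
  expect_error(observed_study("s3", "x", "oral", 1, -1, 2), "> 0")
})
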