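#' Construct a hepatocyte induction dataset
#'
#' One concentration-response series of fold-induction over vehicle control
#' for a single inducer, donor and endpoint.
#'
#' @param inducer character, inducer name.
#' @param donor_id character, hepatocyte donor identifier.
#' @param endpoint `"mRNA"` or `"activity"`.
#' @param concentrations numeric vector of inducer concentrations (uM),
#'   strictly positive, unique within a replicate.
#' @param fold_response numeric vector of fold-over-vehicle-control values
#'   (dimensionless, > 0), paired with `concentrations`.
#' @param replicate_id optional integer replicate labels (same length as
#'   `concentrations`); concentrations must be unique within a replicate.
#' @return An object of class `induction_dataset`.
#' @export
induction_dataset <- function(inducer, donor_id, endpoint = c("mRNA", "activity"),
                              concentrations, fold_response,
                              replicate_id = NULL) {
  endpoint <- match.arg(endpoint)
  concentrations <- as.numeric(concentrations)
  fold_response <- as.numeric(fold_response)
  if (length(concentrations) != length(fold_response))
    stop("concentrations and fold_response must have the same length")
  if (any(!is.finite(concentrations)) || any(concentrations <= 0))
    stop("concentrations must be finite and strictly positive")
  if (any(!is.finite(fold_response)) || any(fold_response <= 0))
    stop("fold_response must be finite and strictly positive")
  if (is.null(replicate_id)) replicate_id <- rep(1L, length(concentrations))
  if (length(replicate_id) != length(concentrations))
    stop("replicate_id must match the length of concentrations")
  for (r in unique(replicate_id)) {
    cc <- concentrations[replicate_id == r]
    if (anyDuplicated(cc))
      stop("concentrations must be unique within a replicate")
  }
  structure(
    list(inducer = as.character(inducer), donor_id = as.character(donor_id),
         endpoint = endpoint, concentrations = concentrations,
         fold_response = fold_response, replicate_id = as.integer(replicate_id)),
    class = "induction_dataset")
}

#' @export
print.induction_dataset <- function(x, ...) {
  cat(sprintf("<induction_dataset> %s / donor %s / %s: %d points, %d distinct conc\n",
              x$inducer, x$donor_id, x$endpoint, length(x$concentrations),
              length(unique(x$concentrations))))
  invisible(x)
}

#' Sigmoidal fold-induction curve
#'
#' Evaluates `baseline + (Ind_max - baseline) * C^hill / (IndC_50^hill + C^hill)`.
#'
#' @param conc concentration (uM), non-negative.
#' @param baseline fitted fold at zero concentration.
#' @param Ind_max maximal fold induction (curve top).
#' @param IndC_50 concentration at half-maximal induction (uM).
#' @param hill Hill exponent.
#' @return fold induction (dimensionless).
#' @export
induction_curve <- function(conc, baseline, Ind_max, IndC_50, hill = 1) {
  if (any(conc < 0)) stop("conc must be non-negative")
  ch <- conc^hill
  baseline + (Ind_max - baseline) * ch / (IndC_50^hill + ch)
}

.new_induction_fit <- function(pars, se, rss, n_points, model, converged,
                               data, flags = character()) {
  structure(
    list(Ind_max = unname(pars["Ind_max"]), IndC_50 = unname(pars["IndC_50"]),
         hill = unname(pars["hill"]), baseline = unname(pars["baseline"]),
         se_Ind_max = unname(se["Ind_max"]), se_IndC_50 = unname(se["IndC_50"]),
         rss = rss, n_points = n_points, model = model, converged = converged,
         flags = flags,
         inducer = data$inducer, donor_id = data$donor_id,
         endpoint = data$endpoint),
    class = "induction_fit")
}

#' @export
print.induction_fit <- function(x, ...) {
  cat(sprintf(
    "<induction_fit> %s/%s/%s [%s]: Ind_max=%.4g (se %.3g), IndC_50=%.4g uM (se %.3g), hill=%.3g, baseline=%.3g, rss=%.3g%s\n",
    x$inducer, x$donor_id, x$endpoint, x$model, x$Ind_max, x$se_Ind_max,
    x$IndC_50, x$se_IndC_50, x$hill, x$baseline, x$rss,
    if (length(x$flags)) paste0(" [", paste(x$flags, collapse = ","), "]") else ""))
  invisible(x)
}

# residual-sum-of-squares objective on (baseline, Ind_max, IndC_50[, hill])
.sigmoid_rss <- function(p, conc, fold, fix_hill) {
  h <- if (fix_hill) 1 else p[4]
  pred <- induction_curve(conc, p[1], p[2], p[3], h)
  sum((fold - pred)^2)
}

#' Fit a sigmoidal Emax model to fold-induction data
#'
#' Least-squares fit of
#' `fold(C) = baseline + (Ind_max - baseline) * C^hill / (IndC_50^hill + C^hill)`.
#' The three-parameter model fixes the Hill exponent at 1; the
#' four-parameter model frees it. `Ind_max` is the curve top in fold units
#' (not corrected for baseline). The baseline is a free parameter bounded
#' to \[0.5, 2\]. Fitting is unweighted, on linear concentration, with the
#' geometric mean of the tested concentrations as the `IndC_50` start and
#' the maximum observed fold as the `Ind_max` start.
#'
#' Non-convergence of the primary Levenberg-Marquardt fit falls back to a
#' bounded quasi-Newton minimisation; an unrecoverable fit is returned with
#' `converged = FALSE` rather than raising an error. Fits whose `IndC_50`
#' exceeds the highest tested concentration are flagged `"extrapolated"`;
#' flat or unstable fits are flagged `"ill_conditioned"`.
#'
#' @param data an [induction_dataset()].
#' @param model `"three_param"` (hill fixed at 1) or `"four_param"`.
#' @return An object of class `induction_fit` with elements `Ind_max`,
#'   `IndC_50`, `hill`, `baseline`, `se_Ind_max`, `se_IndC_50`, `rss`,
#'   `n_points`, `converged` and `flags`.
#' @export
fit_sigmoid <- function(data, model = c("three_param", "four_param")) {
  model <- match.arg(model)
  stopifnot(inherits(data, "induction_dataset"))
  conc <- data$concentrations
  fold <- data$fold_response
  if (length(unique(conc)) < 4)
    stop("at least 4 distinct concentrations are required for fitting")
  n_free <- if (model == "three_param") 3L else 4L
  if (length(conc) <= n_free)
    stop("fewer data points than free parameters")
  fix_hill <- model == "three_param"

  # vehicle control anchors the baseline near 1; log-spaced multi-start on
  # IndC_50 around the geometric mean of the tested grid
  c50_gm <- exp(mean(log(conc)))
  start <- c(baseline = min(max(min(fold, 1), 0.5), 2),
             Ind_max = max(max(fold), 1),
             IndC_50 = c50_gm,
             hill = 1)
  lower <- c(0.5, 1, 1e-9, 0.2)
  upper <- c(2, Inf, Inf, 8)
  if (fix_hill) {
    start <- start[1:3]; lower <- lower[1:3]; upper <- upper[1:3]
  }

  fml <- if (fix_hill) {
    fold ~ baseline + (Ind_max - baseline) * conc / (IndC_50 + conc)
  } else {
    fold ~ baseline + (Ind_max - baseline) * conc^hill / (IndC_50^hill + conc^hill)
  }
  df <- data.frame(conc = conc, fold = fold)

  # Levenberg-Marquardt without box constraints (its active-set handling
  # can stall on a bound); a solution outside the bounds is discarded in
  # favour of the bounded quasi-Newton fallback below
  fit <- NULL
  clipped_start <- NULL
  for (c50_start in c50_gm * c(1, 0.1, 10, 0.01)) {
    st <- start
    st["IndC_50"] <- c50_start
    cand <- tryCatch(
      minpack.lm::nlsLM(
        fml, data = df, start = as.list(st),
        control = minpack.lm::nls.lm.control(
          maxiter = 500, ftol = 1e-14, ptol = 1e-14)),
      error = function(e) NULL)
    if (!is.null(cand)) {
      cf <- coef(cand)
      inb <- all(cf >= lower - 1e-9) && all(cf <= upper + 1e-9)
      if (inb && (is.null(fit) ||
                  sum(resid(cand)^2) < sum(resid(fit)^2) - 1e-12))
        fit <- cand
      if (!inb && is.null(clipped_start))
        clipped_start <- pmin(pmax(cf, lower + 1e-8),
                              pmin(upper, 1e6)) # seed for the bounded path
    }
  }

  flags <- character()
  if (!is.null(fit)) {
    cf <- coef(fit)
    pars <- c(baseline = unname(cf["baseline"]), Ind_max = unname(cf["Ind_max"]),
              IndC_50 = unname(cf["IndC_50"]),
              hill = if (fix_hill) 1 else unname(cf["hill"]))
    se_all <- tryCatch(sqrt(diag(vcov(fit))), error = function(e) NULL)
    se <- c(Ind_max = NA_real_, IndC_50 = NA_real_)
    if (!is.null(se_all)) {
      se["Ind_max"] <- unname(se_all["Ind_max"])
      se["IndC_50"] <- unname(se_all["IndC_50"])
    }
    rss <- sum(resid(fit)^2)
    converged <- TRUE
  } else {
    # bounded quasi-Newton fallback (with restarts until the optimum is
    # stable), standard errors from the numerical Hessian
    run_op <- function(st) tryCatch(
      optim(st, .sigmoid_rss, conc = conc, fold = fold, fix_hill = fix_hill,
            method = "L-BFGS-B", lower = lower, upper = upper,
            control = list(maxit = 5000), hessian = TRUE),
      error = function(e) NULL)
    cands <- list()
    for (st in Filter(Negate(is.null), list(clipped_start, start))) {
      cand <- run_op(st)
      for (k in 1:2) { # polish: restart only while it still improves
        if (is.null(cand)) break
        again <- run_op(cand$par)
        if (is.null(again) || again$value >= cand$value - 1e-12) {
          # a restart that cannot improve the objective is stationary,
          # whatever termination code the line search reports
          if (!is.null(again) &&
              abs(again$value - cand$value) <= 1e-10 * (1 + abs(cand$value)))
            cand$convergence <- 0L
          break
        }
        cand <- again
      }
      if (!is.null(cand)) cands[[length(cands) + 1]] <- cand
    }
    op <- NULL
    if (length(cands)) {
      best <- which.min(vapply(cands, `[[`, numeric(1), "value"))
      op <- cands[[best]]
      # a line-search abort at an optimum another start reached cleanly
      # still counts as converged
      if (any(vapply(cands, function(cc)
            cc$convergence == 0 && cc$value <= op$value + 1e-8, logical(1))))
        op$convergence <- 0L
    }
    if (is.null(op)) {
      pars <- c(baseline = 1, Ind_max = max(fold), IndC_50 = start["IndC_50"],
                hill = 1)
      return(.new_induction_fit(pars, c(Ind_max = Inf, IndC_50 = Inf),
                                rss = NA_real_, n_points = length(conc),
                                model = model, converged = FALSE, data = data,
                                flags = "failed"))
    }
    p <- op$par
    pars <- c(baseline = unname(p[1]), Ind_max = unname(p[2]),
              IndC_50 = unname(p[3]), hill = if (fix_hill) 1 else unname(p[4]))
    rss <- op$value
    dof <- max(length(conc) - n_free, 1)
    s2 <- rss / dof
    cov <- tryCatch(solve(op$hessian / 2) * s2, error = function(e) NULL)
    if (is.null(cov) || any(!is.finite(diag(cov))) || any(diag(cov) < 0)) {
      se <- c(Ind_max = Inf, IndC_50 = Inf)
    } else {
      sev <- sqrt(diag(cov))
      se <- c(Ind_max = unname(sev[2]), IndC_50 = unname(sev[3]))
    }
    converged <- op$convergence == 0
  }

  if (pars["IndC_50"] > max(conc)) flags <- c(flags, "extrapolated")
  if (!all(is.finite(se)) || se["IndC_50"] >= pars["IndC_50"] ||
      (pars["Ind_max"] - pars["baseline"]) < 0.1)
    flags <- c(flags, "ill_conditioned")

  .new_induction_fit(pars, se, rss, length(conc), model, converged, data, flags)
}

#' Evaluate a fitted induction curve
#'
#' @param fit an `induction_fit`.
#' @param conc concentration (uM), non-negative; vectorised.
#' @return predicted fold induction; `conc = 0` returns the baseline, and
#'   the prediction is monotone non-decreasing in `conc`.
#' @export
predict_fold <- function(fit, conc) {
  stopifnot(inherits(fit, "induction_fit"))
  if (any(conc < 0)) stop("conc must be non-negative")
  induction_curve(conc, fit$baseline, fit$Ind_max, fit$IndC_50, fit$hill)
}

#' Aggregate per-donor induction fits
#'
#' Arithmetic mean and sample (n-1) standard deviation of `Ind_max` and
#' `IndC_50` across donors sharing one inducer and endpoint. Failed
#' (non-converged) fits are excluded with a warning; with a single donor
#' the standard deviations are `NA`.
#'
#' @param fits a list of `induction_fit` objects.
#' @return An object of class `donor_summary` with the mean/sd fields and
#'   `n_donors`.
#' @export
summarize_donors <- function(fits) {
  if (length(fits) == 0) stop("empty fit list")
  stopifnot(all(vapply(fits, inherits, logical(1), "induction_fit")))
  ep <- unique(vapply(fits, `[[`, character(1), "endpoint"))
  ind <- unique(vapply(fits, `[[`, character(1), "inducer"))
  if (length(ep) > 1) stop("mixed endpoints in donor summary")
  if (length(ind) > 1) stop("mixed inducers in donor summary")
  ok <- vapply(fits, `[[`, logical(1), "converged")
  if (any(!ok)) {
    warning(sprintf("excluding %d non-converged fit(s) from donor summary",
                    sum(!ok)))
    fits <- fits[ok]
  }
  if (length(fits) == 0) stop("no converged fits to summarize")
  im <- vapply(fits, `[[`, numeric(1), "Ind_max")
  ic <- vapply(fits, `[[`, numeric(1), "IndC_50")
  n <- length(fits)
  structure(
    list(inducer = ind, endpoint = ep,
         mean_Ind_max = mean(im), sd_Ind_max = if (n > 1) sd(im) else NA_real_,
         mean_IndC_50 = mean(ic), sd_IndC_50 = if (n > 1) sd(ic) else NA_real_,
         n_donors = n),
    class = "donor_summary")
}

#' @export
print.donor_summary <- function(x, ...) {
  cat(sprintf(
    "<donor_summary> %s/%s (n=%d donors): Ind_max %.3g +/- %.3g, IndC_50 %.3g +/- %.3g uM\n",
    x$inducer, x$endpoint, x$n_donors, x$mean_Ind_max, x$sd_Ind_max,
    x$mean_IndC_50, x$sd_IndC_50))
  invisible(x)
}
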