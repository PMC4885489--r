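#' Reciprocal AUC ratio
#'
#' `AUC_control / AUC_induced`; exceeds 1 in the presence of an enzyme
#' inducer (reporting convention used throughout the package).
#'
#' @param AUC_control,AUC_induced positive AUCs in the same unit.
#' @return the reciprocal ratio.
#' @export
reciprocal_ratio <- function(AUC_control, AUC_induced) {
  if (any(AUC_control <= 0) || any(AUC_induced <= 0))
    stop("AUCs must be > 0")
  AUC_control / AUC_induced
}

#' Geometric mean fold error
#'
#' `10 ^ mean(|log10(predicted / observed)|)`. Equals 1 if and only if
#' every prediction matches its observation; symmetric in over- and
#' under-prediction.
#'
#' @param predicted,observed positive numeric vectors of equal length.
#' @return GMFE (>= 1).
#' @export
gmfe <- function(predicted, observed) {
  if (length(predicted) == 0) stop("empty input")
  if (length(predicted) != length(observed)) stop("length mismatch")
  if (any(predicted <= 0) || any(observed <= 0)) stop("values must be > 0")
  10^mean(abs(log10(predicted / observed)))
}

#' Root-mean-square error of predicted vs observed ratios
#'
#' @param predicted,observed numeric vectors of equal length.
#' @return RMSE.
#' @export
rmse <- function(predicted, observed) {
  if (length(predicted) == 0) stop("empty input")
  if (length(predicted) != length(observed)) stop("length mismatch")
  sqrt(mean((predicted - observed)^2))
}

#' Observation-scaled acceptance limits
#'
#' For an observed reciprocal ratio `R >= 1` the limit is
#' `L = (delta + 2 * (R - 1)) / R` and the acceptance interval
#' `[R / L, R * L]`. The interval collapses to the point `R = 1` for no
#' interaction (at `delta = 1`) and widens towards the classical two-fold
#' window as `R` grows, making it a more sensitive concordance measure
#' for small interactions. Ratios below 1 are transformed through their
#' reciprocal before the limit is applied.
#'
#' @param R observed ratio(s).
#' @param delta variability allowance (>= 1); `1.25` by default.
#' @return data.frame with columns `lower`, `upper`.
#' @export
acceptance_limits <- function(R, delta = 1.25) {
  if (any(delta < 1)) stop("delta must be >= 1")
  flip <- R < 1
  Rw <- ifelse(flip, 1 / R, R)
  L <- (delta + 2 * (Rw - 1)) / Rw
  lo <- Rw / L
  hi <- Rw * L
  data.frame(lower = ifelse(flip, 1 / hi, lo),
             upper = ifelse(flip, 1 / lo, hi))
}

#' Is each prediction within the acceptance limits of its observation?
#'
#' @param predicted,observed ratio vectors.
#' @param delta see [acceptance_limits()].
#' @return logical vector.
#' @export
within_limits <- function(predicted, observed, delta = 1.25) {
  lim <- acceptance_limits(observed, delta)
  predicted >= lim$lower & predicted <= lim$upper
}

#' Geometric mean of observed fold-induction ratios
#'
#' Unweighted by default: `exp(mean(log(ratios)))`. Sample-size weights
#' may be supplied.
#'
#' @param ratios positive ratios.
#' @param weights optional non-negative weights.
#' @return the geometric mean.
#' @export
meta_geomean <- function(ratios, weights = NULL) {
  if (length(ratios) == 0) stop("empty input")
  if (any(ratios <= 0)) stop("ratios must be > 0")
  if (is.null(weights)) return(exp(mean(log(ratios))))
  if (length(weights) != length(ratios) || any(weights < 0))
    stop("invalid weights")
  exp(sum(weights * log(ratios)) / sum(weights))
}

#' Prediction accuracy summary
#'
#' @param predicted,observed ratio vectors.
#' @param delta acceptance-limit allowance.
#' @param label optional subgroup/model label.
#' @return one-row data.frame with `label`, `n`, `GMFE`, `RMSE`,
#'   `pct_within_limits`.
#' @export
accuracy_summary <- function(predicted, observed, delta = 1.25, label = "") {
  data.frame(label = label, n = length(predicted),
             GMFE = gmfe(predicted, observed),
             RMSE = rmse(predicted, observed),
             pct_within_limits =
               100 * mean(within_limits(predicted, observed, delta)))
}

.study_subgroups <- function(victim, route) {
  iv <- route != "oral"
  grp <- c("all", if (iv) "all_iv" else "all_oral")
  if (victim == "midazolam")
    grp <- c(grp, if (iv) "iv_MDZ" else "oral_MDZ", "all_MDZ")
  grp
}

#' Sweep rifampicin induction models over a study set
#'
#' Runs every study design under each requested rifampicin induction
#' model (see [reference_set()]), pools predicted reciprocal AUC ratios
#' across trials, joins the observed ratios, and summarises accuracy
#' (GMFE, RMSE, percent within acceptance limits) per model and subgroup
#' (i.v. MDZ, oral MDZ, all i.v., all oral, all).
#'
#' @param designs list of [ddi_study_design()]s carrying `observed`
#'   records and victim compound names in their victim regimens.
#' @param models character vector of model labels (subset of A-G).
#' @param perpetrator rifampicin [compound_profile()]; its induction
#'   parameters are replaced per model.
#' @param victims named list of victim profiles keyed by compound name;
#'   defaults to the curated library.
#' @param system,enzyme,cv,options,seed forwarded to [run_study()].
#' @param n_subjects,n_trials optional overrides of each design's sizes.
#' @param delta acceptance-limit allowance.
#' @return list with `per_study` (one row per study x model) and
#'   `summary` (accuracy per model x subgroup) data.frames.
#' @export
scenario_sweep <- function(designs, models = c("model_A", "model_C"),
                           perpetrator = perpetrator_profile("rifampicin"),
                           victims = NULL, system = system_parameters(),
                           enzyme = enzyme_settings(), cv = population_cv(),
                           options = sim_options(), seed = 1,
                           n_subjects = NULL, n_trials = NULL, delta = 1.25) {
  if (is.null(victims)) {
    vn <- unique(vapply(designs, function(d) d$victim_regimen$compound,
                        character(1)))
    victims <- setNames(lapply(vn, victim_profile), vn)
  }
  per <- list()
  for (mi in seq_along(models)) {
    perp_m <- set_induction(perpetrator, reference_set(models[mi]))
    for (si in seq_along(designs)) {
      d <- designs[[si]]
      if (is.null(d$observed)) {
        warning("study ", d$study_id, " has no observed data; skipped")
        next
      }
      if (!is.null(n_subjects)) d$n_subjects <- n_subjects
      if (!is.null(n_trials)) d$n_trials <- n_trials
      vic <- victims[[d$victim_regimen$compound]]
      if (is.null(vic)) stop("no victim profile for ", d$victim_regimen$compound)
      res <- run_study(d, vic, perp_m, system = system, enzyme = enzyme,
                       cv = cv, seed = seed + si, options = options)
      pr <- pool_ratios(res)
      per[[length(per) + 1]] <- data.frame(
        study_id = d$study_id, model = models[mi],
        victim = vic$name, route = d$victim_regimen$route,
        predicted_ratio = pr$pooled_ratio,
        observed_ratio = observed_ratio(d$observed),
        n_subjects = d$n_subjects, n_trials = d$n_trials)
    }
  }
  per <- do.call(rbind, per)
  per$fold_error <- per$predicted_ratio / per$observed_ratio
  per$within_limits <- within_limits(per$predicted_ratio, per$observed_ratio,
                                     delta)
  summ <- list()
  for (m in unique(per$model)) {
    pm <- per[per$model == m, ]
    groups <- unique(unlist(Map(.study_subgroups, pm$victim, pm$route)))
    for (g in groups) {
      keep <- vapply(seq_len(nrow(pm)), function(i)
        g %in% .study_subgroups(pm$victim[i], pm$route[i]), logical(1))
      s <- accuracy_summary(pm$predicted_ratio[keep], pm$observed_ratio[keep],
                            delta, label = g)
      s$model <- m
      s$geomean_predicted <- meta_geomean(pm$predicted_ratio[keep])
      s$geomean_observed <- meta_geomean(pm$observed_ratio[keep])
      summ[[length(summ) + 1]] <- s
    }
  }
  summ <- do.call(rbind, summ)
  list(per_study = per, summary = summ[, c("model", "label", "n", "GMFE",
                                           "RMSE", "pct_within_limits",
                                           "geomean_predicted",
                                           "geomean_observed")])
}

#' One-dimensional sensitivity sweep
#'
#' Re-runs one study design across values of an enzyme-turnover or
#' gut-binding parameter and reports the predicted pooled reciprocal
#' ratio per value. By default a single reference subject (CVs of 0) is
#' simulated so the trend is noise-free.
#'
#' @param parameter `"kdeg_H"`, `"kdeg_G"` or `"fu_gut_IN"` (the
#'   perpetrator's enterocyte unbound fraction).
#' @param values positive parameter values to sweep.
#' @param design a [ddi_study_design()].
#' @param victim,perpetrator compound profiles.
#' @param system,enzyme,cv,options,seed forwarded to [run_study()].
#' @return data.frame with `parameter`, `value`, `predicted_ratio`.
#' @export
sensitivity_sweep <- function(parameter = c("kdeg_H", "kdeg_G", "fu_gut_IN"),
                              values, design, victim, perpetrator,
                              system = system_parameters(),
                              enzyme = enzyme_settings(),
                              cv = population_cv(cv_enz_H = 0, cv_enz_G = 0,
                                                 cv_clu = 0, cv_ka = 0,
                                                 cv_vss = 0, cv_qh = 0,
                                                 bw_cv = 0),
                              options = sim_options(), seed = 1) {
  parameter <- match.arg(parameter)
  if (any(values <= 0)) stop("sweep values must be positive")
  if (parameter == "fu_gut_IN" && any(values > 1))
    stop("fu_gut_IN must be in (0, 1]")
  rows <- lapply(values, function(v) {
    enz <- enzyme
    perp <- perpetrator
    if (parameter == "kdeg_H") enz$kdeg_H <- v
    if (parameter == "kdeg_G") enz$kdeg_G <- v
    if (parameter == "fu_gut_IN") perp$fu_gut <- v
    res <- run_study(design, victim, perp, system = system, enzyme = enz,
                     cv = cv, seed = seed, options = options)
    data.frame(parameter = parameter, value = v,
               predicted_ratio = pool_ratios(res)$pooled_ratio)
  })
  do.call(rbind, rows)
}
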