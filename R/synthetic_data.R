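#' Specification for a synthetic hepatocyte induction experiment
#'
#' Defines the ground truth and variability structure used by
#' [make_induction_dataset()]. Defaults emulate the bundled rifampicin
#' activity data: donor-to-donor log-normal spread on `Ind_max - 1` and
#' `IndC_50` with CVs matching the donor-mean table (sd/mean of about
#' 0.34 and 0.33), multiplicative residual noise on the fold values, and
#' the seven-point rifampicin concentration grid.
#'
#' @param inducer,endpoint labels.
#' @param Ind_max,IndC_50,hill generating truth (population means).
#' @param grid concentration grid (uM).
#' @param n_donors number of donors.
#' @param cv_Ind_max,cv_IndC_50 donor-level CVs (log-normal, applied to
#'   `Ind_max - 1` so `Ind_max >= 1` by construction; arithmetic-mean
#'   preserving).
#' @param noise_cv multiplicative residual CV on fold values (median
#'   preserving).
#' @param seed integer seed.
#' @return list of class `synthetic_induction_spec`.
#' @export
synthetic_induction_spec <- function(inducer = "rifampicin",
                                     endpoint = "activity",
                                     Ind_max = 22.7, IndC_50 = 0.30,
                                     hill = 1,
                                     grid = concentration_grid(inducer),
                                     n_donors = 4,
                                     cv_Ind_max = 0.34, cv_IndC_50 = 0.33,
                                     noise_cv = 0.15, seed = 1) {
  if (Ind_max < 1 || IndC_50 <= 0 || hill <= 0) stop("invalid truth parameters")
  if (any(c(cv_Ind_max, cv_IndC_50, noise_cv) < 0)) stop("CVs must be >= 0")
  structure(list(inducer = inducer, endpoint = endpoint, Ind_max = Ind_max,
                 IndC_50 = IndC_50, hill = hill, grid = grid,
                 n_donors = n_donors, cv_Ind_max = cv_Ind_max,
                 cv_IndC_50 = cv_IndC_50, noise_cv = noise_cv, seed = seed),
            class = "synthetic_induction_spec")
}

# arithmetic-mean-preserving log-normal draw around m with coefficient cv
.lnorm_mean <- function(n, m, cv) {
  if (cv <= 0) return(rep(m, n))
  sdlog <- sqrt(log(1 + cv^2))
  rlnorm(n, meanlog = log(m) - sdlog^2 / 2, sdlog = sdlog)
}

#' Generate synthetic per-donor induction datasets
#'
#' Donor-level true parameters are drawn log-normally about the spec
#' truth (on `Ind_max - 1` and `IndC_50`), fold values are the sigmoid
#' curve times multiplicative log-normal noise, and the baseline is
#' anchored at 1 (vehicle control).
#'
#' @param spec a [synthetic_induction_spec()].
#' @return list of [induction_dataset()]s, one per donor, with the donor
#'   truths attached as the `"truth"` attribute.
#' @export
make_induction_dataset <- function(spec) {
  stopifnot(inherits(spec, "synthetic_induction_spec"))
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(spec$seed)
  emax_d <- .lnorm_mean(spec$n_donors, spec$Ind_max - 1, spec$cv_Ind_max)
  c50_d <- .lnorm_mean(spec$n_donors, spec$IndC_50, spec$cv_IndC_50)
  sdlog <- if (spec$noise_cv > 0) sqrt(log(1 + spec$noise_cv^2)) else 0
  out <- vector("list", spec$n_donors)
  truth <- data.frame(donor = seq_len(spec$n_donors),
                      Ind_max = 1 + emax_d, IndC_50 = c50_d)
  for (d in seq_len(spec$n_donors)) {
    mu <- induction_curve(spec$grid, baseline = 1, Ind_max = 1 + emax_d[d],
                          IndC_50 = c50_d[d], hill = spec$hill)
    fold <- mu * exp(rnorm(length(mu), 0, sdlog))
    out[[d]] <- induction_dataset(spec$inducer, paste0("D", d), spec$endpoint,
                                  spec$grid, fold)
  }
  attr(out, "truth") <- truth
  out
}

#' Synthetic compound profile archetypes
#'
#' Internally consistent example profiles for pipeline testing:
#' \describe{
#'   \item{`midazolam_like`}{oral victim targeting `fm_CYP3A4` about 0.9
#'     and baseline `F_G` about 0.5.}
#'   \item{`rifampicin_like`}{perpetrator with fixed (non-CYP3A4) hepatic
#'     clearance, so no autoinduction, and base-model induction
#'     parameters.}
#'   \item{`high_fg_victim` / `low_fg_victim`}{victims bracketing the gut
#'     extraction range (baseline `F_G` about 0.94 / 0.30).}
#'   \item{`autoinducer`}{perpetrator whose elimination is largely
#'     CYP3A4-mediated and which induces CYP3A4, so accumulation on
#'     multiple dosing is reversed by autoinduction.}
#' }
#'
#' @param archetype archetype name.
#' @param overrides named list of [compound_profile()] fields to replace.
#' @return a [compound_profile()].
#' @export
make_compound_profile <- function(archetype = c("midazolam_like",
                                                "rifampicin_like",
                                                "high_fg_victim",
                                                "low_fg_victim",
                                                "autoinducer"),
                                  overrides = NULL) {
  archetype <- match.arg(archetype)
  base <- switch(archetype,
    midazolam_like = victim_profile("midazolam"),
    rifampicin_like = perpetrator_profile("rifampicin"),
    high_fg_victim = {
      p <- victim_profile("alprazolam")
      p$name <- "high_fg_victim"
      p
    },
    low_fg_victim = {
      sys <- system_parameters()
      compound_profile(
        "low_fg_victim", MW = 400, fu_p = 0.05, BP = 0.8, fu_gut = 1,
        Kp_liver = 2, ka = 1.5, Fa = 0.9, Vss = 1.2,
        elimination = list(
          pathway_clearance("CYP3A4", "liver", CLu_int = 900),
          pathway_clearance("other", "liver", CLu_int = 100),
          # fu_gut * CLuG = Q_gut * (1 - FG) / FG with FG = 0.30
          pathway_clearance("CYP3A4", "gut",
                            CLu_int = sys$Q_gut * (1 - 0.30) / 0.30)))
    },
    autoinducer = compound_profile(
      "autoinducer", MW = 400, fu_p = 0.10, BP = 1, fu_gut = 1,
      Kp_liver = 1.5, ka = 1, Fa = 0.9, Vss = 1.0,
      elimination = list(
        pathway_clearance("CYP3A4", "liver", CLu_int = 40),
        pathway_clearance("other", "liver", CLu_int = 5)),
      induction = list(liver = c(Ind_max = 10, IndC_50 = 0.5),
                       gut = c(Ind_max = 10, IndC_50 = 0.5))))
  if (!is.null(overrides)) {
    args <- unclass(base)
    if (length(setdiff(names(overrides), names(args))))
      stop("unknown override field(s): ",
           paste(setdiff(names(overrides), names(args)), collapse = ", "))
    args[names(overrides)] <- overrides
    base <- do.call(compound_profile, args)
  }
  base
}

#' Specification for a synthetic DDI study set
#'
#' @param n_studies number of synthetic studies.
#' @param victim_archetype,perp_archetype archetypes for
#'   [make_compound_profile()].
#' @param truth induction truth for the perpetrator
#'   (`list(liver = c(Ind_max, IndC_50), gut = ...)` or a
#'   [reference_set()] output).
#' @param perp_dose_mg,victim_dose_mg doses (mg).
#' @param perp_days_range range of perpetrator dosing durations (days)
#'   spanned across the study set.
#' @param stagger victim dose offset (h) after the last perpetrator dose.
#' @param n_subjects subjects per study.
#' @param noise_cv log-normal observation noise CV applied independently
#'   to each arm's AUC (crossover read-out noise), not to ratios.
#' @param seed integer seed.
#' @return list of class `synthetic_study_spec`.
#' @export
synthetic_study_spec <- function(n_studies = 6,
                                 victim_archetype = "midazolam_like",
                                 perp_archetype = "rifampicin_like",
                                 truth = reference_set("model_C"),
                                 perp_dose_mg = 600, victim_dose_mg = 7.5,
                                 perp_days_range = c(5, 10), stagger = 12,
                                 n_subjects = 10, noise_cv = 0.3, seed = 1) {
  if (noise_cv < 0) stop("noise_cv must be >= 0")
  structure(list(n_studies = n_studies, victim_archetype = victim_archetype,
                 perp_archetype = perp_archetype, truth = truth,
                 perp_dose_mg = perp_dose_mg, victim_dose_mg = victim_dose_mg,
                 perp_days_range = perp_days_range, stagger = stagger,
                 n_subjects = n_subjects, noise_cv = noise_cv, seed = seed),
            class = "synthetic_study_spec")
}

#' Generate a synthetic study table with known ground truth
#'
#' "Observed" AUCs are produced by simulating the reference subject at
#' the truth induction parameters and multiplying each arm's AUC by
#' independent log-normal observation noise. The truth is recorded so
#' recovery and closure tests can compare predictions against it.
#'
#' @param spec a [synthetic_study_spec()].
#' @param system,enzyme,options forwarded to the simulator.
#' @return list with `designs` (each carrying its [observed_study()]),
#'   `observed`, and `truth` (the generating induction parameters and the
#'   noise-free reference ratios).
#' @export
make_study_table <- function(spec, system = system_parameters(),
                             enzyme = enzyme_settings(),
                             options = sim_options()) {
  stopifnot(inherits(spec, "synthetic_study_spec"))
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(spec$seed)
  victim <- make_compound_profile(spec$victim_archetype)
  perp <- set_induction(make_compound_profile(spec$perp_archetype), spec$truth)
  days <- round(seq(spec$perp_days_range[1], spec$perp_days_range[2],
                    length.out = spec$n_studies))
  sdlog <- if (spec$noise_cv > 0) sqrt(log(1 + spec$noise_cv^2)) else 0
  designs <- vector("list", spec$n_studies)
  observed <- vector("list", spec$n_studies)
  true_ratio <- numeric(spec$n_studies)
  cv0 <- population_cv(0, 0, 0, 0, 0, 0, bw_cv = 0)
  for (i in seq_len(spec$n_studies)) {
    d <- ddi_study_design(
      study_id = sprintf("synth_%02d", i),
      perpetrator_regimen = dose_regimen(perp$name, spec$perp_dose_mg,
                                         "oral", n_doses = days[i],
                                         interval = 24),
      victim_regimen = dose_regimen(victim$name, spec$victim_dose_mg, "oral"),
      stagger = spec$stagger, n_subjects = spec$n_subjects, n_trials = 1)
    ref <- run_study(d, victim, perp, system = system, enzyme = enzyme,
                     cv = cv0, seed = spec$seed,
                     subjects = sample_population(
                       ddi_study_design(d$study_id, d$perpetrator_regimen,
                                        d$victim_regimen, d$stagger,
                                        n_subjects = 1, n_trials = 1),
                       cv0, spec$seed),
                     options = options)
    true_ratio[i] <- ref$ratio_recip[1]
    auc_c <- ref$auc_control[1] * exp(rnorm(1, 0, sdlog))
    auc_i <- ref$auc_induced[1] * exp(rnorm(1, 0, sdlog))
    obs <- observed_study(d$study_id, victim$name, "oral", spec$n_subjects,
                          auc_c, auc_i)
    d$observed <- obs
    designs[[i]] <- d
    observed[[i]] <- obs
  }
  list(designs = designs, observed = observed,
       truth = list(induction = perp$induction, true_ratio = true_ratio))
}
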