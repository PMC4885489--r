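#' Observed clinical DDI study record
#'
#' One published study's observed exposure of a CYP3A4 probe substrate
#' before and after multiple dosing of an inducer. The reporting
#' convention is the reciprocal AUC ratio `AUC_control / AUC_induced`,
#' which exceeds 1 under induction. Where a study escalated the victim
#' dose between arms, the printed ratio (derived from clearances) is the
#' authoritative value and the AUC quotient is not meaningful.
#'
#' @param study_id identifier.
#' @param victim victim compound label.
#' @param route victim route (`"oral"`, `"iv_bolus"`, `"iv_infusion"`).
#' @param n number of subjects.
#' @param AUC_control,AUC_induced observed AUCs (any consistent unit).
#' @param ratio_printed the published reciprocal ratio as a string (kept
#'   as printed so its precision is known), or `NULL`.
#' @param dose_escalated logical; victim dose differed between arms.
#' @param auc_unit unit label.
#' @return object of class `observed_study`.
#' @export
observed_study <- function(study_id, victim, route, n, AUC_control,
                           AUC_induced, ratio_printed = NULL,
                           dose_escalated = FALSE, auc_unit = "") {
  if (AUC_control <= 0 || AUC_induced <= 0) stop("AUCs must be > 0")
  structure(
    list(study_id = study_id, victim = victim, route = route, n = n,
         AUC_control = AUC_control, AUC_induced = AUC_induced,
         ratio_recip = AUC_control / AUC_induced,
         ratio_printed = if (is.null(ratio_printed)) NULL
                         else as.character(ratio_printed),
         dose_escalated = isTRUE(dose_escalated), auc_unit = auc_unit),
    class = "observed_study")
}

#' Authoritative observed reciprocal ratio
#'
#' The printed ratio when available, otherwise the AUC quotient.
#'
#' @param x an `observed_study`.
#' @return numeric reciprocal AUC ratio.
#' @export
observed_ratio <- function(x) {
  stopifnot(inherits(x, "observed_study"))
  if (!is.null(x$ratio_printed)) as.numeric(x$ratio_printed) else x$ratio_recip
}

#' Clinical DDI study design for virtual replication
#'
#' The victim is dosed `stagger` hours after the start of the last
#' scheduled perpetrator dose (negative stagger: victim before that dose).
#' The control arm doses the victim alone; both arms share subjects
#' (paired crossover design).
#'
#' @param study_id identifier.
#' @param perpetrator_regimen a [dose_regimen()] for the inducer.
#' @param victim_regimen a [dose_regimen()] for the victim; its
#'   `start_time` is set by the design.
#' @param stagger victim dose offset (h) from the last perpetrator dose.
#' @param n_subjects subjects per trial.
#' @param n_trials number of virtual trial replicates (default 10).
#' @param age_range,proportion_female demographic labels (not linked to a
#'   covariate physiology model).
#' @param observed optional [observed_study()].
#' @param ambiguous_stagger logical; simultaneous dosing was assumed for
#'   an ambiguous published stagger.
#' @return object of class `ddi_study_design`.
#' @export
ddi_study_design <- function(study_id, perpetrator_regimen, victim_regimen,
                             stagger = 0, n_subjects = 10, n_trials = 10,
                             age_range = c(18, 55), proportion_female = 0.5,
                             observed = NULL, ambiguous_stagger = FALSE) {
  stopifnot(inherits(perpetrator_regimen, "dose_regimen"),
            inherits(victim_regimen, "dose_regimen"))
  if (n_subjects < 1) stop("n_subjects must be >= 1")
  if (proportion_female < 0 || proportion_female > 1)
    stop("proportion_female must be in [0, 1]")
  structure(
    list(study_id = study_id, perpetrator_regimen = perpetrator_regimen,
         victim_regimen = victim_regimen, stagger = stagger,
         n_subjects = as.integer(n_subjects), n_trials = as.integer(n_trials),
         age_range = age_range, proportion_female = proportion_female,
         observed = observed, ambiguous_stagger = isTRUE(ambiguous_stagger)),
    class = "ddi_study_design")
}

#' Victim dose time implied by a study design
#'
#' @param design a [ddi_study_design()].
#' @return time (h) of the victim dose in the induced arm.
#' @export
victim_dose_time <- function(design) {
  p <- design$perpetrator_regimen
  p$start_time + (p$n_doses - 1) * p$interval + design$stagger
}

#' Population variability configuration
#'
#' Coefficients of variation of the independent log-normal multipliers
#' applied per virtual subject (geometric mean 1), and the body-weight
#' distribution (normal, truncated at +/- 3 SD).
#'
#' @param cv_enz_H,cv_enz_G CV of hepatic/gut baseline CYP3A4 abundance.
#' @param cv_clu CV of pathway intrinsic clearances.
#' @param cv_ka CV of the absorption rate constant.
#' @param cv_vss CV of the distribution volume.
#' @param cv_qh CV of hepatic (and portal) blood flow.
#' @param bw_mean,bw_cv body weight mean (kg) and CV.
#' @return list of class `population_cv`.
#' @export
population_cv <- function(cv_enz_H = 0.45, cv_enz_G = 0.45, cv_clu = 0.30,
                          cv_ka = 0.25, cv_vss = 0.20, cv_qh = 0.15,
                          bw_mean = 70, bw_cv = 0.15) {
  vals <- c(cv_enz_H, cv_enz_G, cv_clu, cv_ka, cv_vss, cv_qh, bw_cv)
  if (any(vals < 0)) stop("CVs must be >= 0")
  structure(list(cv_enz_H = cv_enz_H, cv_enz_G = cv_enz_G, cv_clu = cv_clu,
                 cv_ka = cv_ka, cv_vss = cv_vss, cv_qh = cv_qh,
                 bw_mean = bw_mean, bw_cv = bw_cv),
            class = "population_cv")
}

.lnorm_mult <- function(n, cv) {
  if (cv <= 0) return(rep(1, n))
  sdlog <- sqrt(log(1 + cv^2))
  rlnorm(n, meanlog = 0, sdlog = sdlog)
}

#' Sample a virtual population for a study design
#'
#' Draws `n_trials x n_subjects` virtual subjects with independent
#' log-normal parameter multipliers (geometric mean 1) and truncated-
#' normal body weights. Deterministic given the seed.
#'
#' @param design a [ddi_study_design()].
#' @param cv a [population_cv()].
#' @param seed integer seed.
#' @return data.frame of class `subject_physiology` with one row per
#'   subject: `trial`, `subject`, `bw`, and multipliers `m_enzH`,
#'   `m_enzG`, `m_clu`, `m_ka`, `m_vss`, `m_qh`.
#' @export
sample_population <- function(design, cv = population_cv(), seed = 1) {
  stopifnot(inherits(design, "ddi_study_design"))
  n <- design$n_trials * design$n_subjects
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(seed)
  bw <- rnorm(n, cv$bw_mean, cv$bw_cv * cv$bw_mean)
  lim <- 3 * cv$bw_cv * cv$bw_mean
  bw <- pmin(pmax(bw, cv$bw_mean - lim), cv$bw_mean + lim)
  out <- data.frame(
    trial = rep(seq_len(design$n_trials), each = design$n_subjects),
    subject = seq_len(n), bw = bw,
    m_enzH = .lnorm_mult(n, cv$cv_enz_H), m_enzG = .lnorm_mult(n, cv$cv_enz_G),
    m_clu = .lnorm_mult(n, cv$cv_clu), m_ka = .lnorm_mult(n, cv$cv_ka),
    m_vss = .lnorm_mult(n, cv$cv_vss), m_qh = .lnorm_mult(n, cv$cv_qh))
  attr(out, "seed") <- seed
  class(out) <- c("subject_physiology", class(out))
  out
}

# apply one subject's multipliers to a profile / the system
.subject_profile <- function(profile, subj) {
  if (is.null(profile)) return(NULL)
  profile$elimination <- lapply(profile$elimination, function(p) {
    m <- subj$m_clu
    if (toupper(p$enzyme) == "CYP3A4")
      m <- m * if (p$site == "liver") subj$m_enzH else subj$m_enzG
    if (p$mode == "clint") p$CLu_int <- p$CLu_int * m else p$Vmax <- p$Vmax * m
    p
  })
  profile$ka <- profile$ka * subj$m_ka
  profile$Vss <- profile$Vss * subj$m_vss
  profile
}

.subject_system <- function(system, subj) {
  system$Q_h <- system$Q_h * subj$m_qh
  system$Q_pv <- system$Q_pv * subj$m_qh
  system$body_weight <- subj$bw
  system
}

.subject_auc <- function(sim) {
  m <- sim$victim
  if (is.na(m$AUC_0_inf)) m$AUC_0_t else m$AUC_0_inf
}

#' Run one clinical study design as paired virtual trials
#'
#' Simulates each virtual subject twice: a control arm (victim alone) and
#' an induced arm (perpetrator regimen, then the victim dosed at the
#' design's stagger time). Arms share all subject physiology, matching the
#' crossover designs of the replicated clinical studies.
#'
#' @param design a [ddi_study_design()].
#' @param victim,perpetrator [compound_profile()]s; regimen compound names
#'   in the design must match.
#' @param system [system_parameters()] for the reference subject.
#' @param enzyme [enzyme_settings()].
#' @param cv [population_cv()]; use CVs of 0 for a single reference
#'   subject.
#' @param seed population seed.
#' @param options [sim_options()].
#' @param subjects optional pre-sampled [sample_population()] output.
#' @return data.frame of class `ddi_result` with one row per subject:
#'   AUCs, the predicted reciprocal ratio `ratio_recip`, and Cmax pairs.
#' @export
run_study <- function(design, victim, perpetrator,
                      system = system_parameters(),
                      enzyme = enzyme_settings(), cv = population_cv(),
                      seed = 1, options = sim_options(), subjects = NULL) {
  stopifnot(inherits(design, "ddi_study_design"))
  if (is.null(subjects)) subjects <- sample_population(design, cv, seed)
  tv <- victim_dose_time(design)
  if (tv < 0) stop("victim dose time is negative; check stagger")
  vreg_ctl <- design$victim_regimen
  vreg_ctl$compound <- victim$name
  vreg_ctl$start_time <- 0
  vreg_ind <- vreg_ctl
  vreg_ind$start_time <- tv
  preg <- design$perpetrator_regimen
  preg$compound <- perpetrator$name

  rows <- lapply(seq_len(nrow(subjects)), function(i) {
    subj <- subjects[i, ]
    vic_i <- .subject_profile(victim, subj)
    per_i <- .subject_profile(perpetrator, subj)
    sys_i <- .subject_system(system, subj)
    ctl <- simulate_ddi(vic_i, vreg_ctl, perpetrator = NULL, system = sys_i,
                        enzyme = enzyme, options = options)
    ind <- simulate_ddi(vic_i, list(preg, vreg_ind), perpetrator = per_i,
                        system = sys_i, enzyme = enzyme, options = options)
    data.frame(trial = subj$trial, subject = subj$subject,
               auc_control = .subject_auc(ctl), auc_induced = .subject_auc(ind),
               cmax_control = ctl$victim$C_max, cmax_induced = ind$victim$C_max,
               F_G_control = ctl$victim$F_G, F_G_induced = ind$victim$F_G)
  })
  out <- do.call(rbind, rows)
  out$ratio_recip <- out$auc_control / out$auc_induced
  out$cmax_ratio_recip <- out$cmax_control / out$cmax_induced
  attr(out, "design") <- design
  attr(out, "victim") <- victim$name
  attr(out, "seed") <- attr(subjects, "seed")
  class(out) <- c("ddi_result", class(out))
  out
}

#' Pool per-subject ratios across virtual trials
#'
#' Geometric mean of per-trial geometric means, equally weighted; the
#' pooled value always lies within the range of the trial means.
#'
#' @param result a [run_study()] result (or any data.frame with `trial`
#'   and `ratio_recip`).
#' @param column which ratio column to pool.
#' @return list with `pooled_ratio` and the per-trial geometric means
#'   `trial_ratios`.
#' @export
pool_ratios <- function(result, column = "ratio_recip") {
  tr <- vapply(split(result[[column]], result$trial),
               function(x) exp(mean(log(x))), numeric(1))
  list(pooled_ratio = exp(mean(log(tr))), trial_ratios = tr)
}
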