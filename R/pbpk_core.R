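#' Minimal-PBPK system parameters
#'
#' Flows and volumes of the lumped model structure (gut lumen ->
#' enterocyte -> portal vein -> liver -> systemic). Defaults are adult
#' reference values; the systemic volume itself comes from each compound's
#' `Vss`, so `V_plasma` is informational only.
#'
#' @param Q_h hepatic blood flow (L/h, blood).
#' @param Q_pv portal vein blood flow (L/h); must not exceed `Q_h`.
#' @param Q_gut nominal villous flow driving the gut extraction model (L/h).
#' @param V_plasma plasma volume (L), informational.
#' @param V_liver liver volume (L).
#' @param V_ent enterocyte compartment volume (L).
#' @param V_pv portal vein compartment volume (L).
#' @param body_weight body weight (kg); scales `Vss` and mg/kg doses.
#' @return object of class `system_parameters`.
#' @export
system_parameters <- function(Q_h = 90, Q_pv = 70, Q_gut = 18,
                              V_plasma = 3, V_liver = 1.65,
                              V_ent = 0.5, V_pv = 1.0,
                              body_weight = 70) {
  vals <- c(Q_h, Q_pv, Q_gut, V_plasma, V_liver, V_ent, V_pv, body_weight)
  if (any(!is.finite(vals)) || any(vals <= 0))
    stop("all system parameters must be positive and finite")
  if (Q_pv > Q_h) stop("Q_pv must not exceed Q_h")
  structure(list(Q_h = Q_h, Q_pv = Q_pv, Q_gut = Q_gut, V_plasma = V_plasma,
                 V_liver = V_liver, V_ent = V_ent, V_pv = V_pv,
                 body_weight = body_weight),
            class = "system_parameters")
}

#' Enzyme turnover settings
#'
#' First-order degradation rate constants of active CYP3A4. The baseline
#' amounts are dimensionless (1 by convention) and multiply the CYP3A4
#' pathway clearances.
#'
#' @param kdeg_H hepatic degradation rate constant (1/h).
#' @param kdeg_G gut degradation rate constant (1/h).
#' @param Enz_0_H,Enz_0_G baseline relative amounts (default 1).
#' @return object of class `enzyme_settings`.
#' @export
enzyme_settings <- function(kdeg_H = 0.0193, kdeg_G = 0.03,
                            Enz_0_H = 1, Enz_0_G = 1) {
  if (kdeg_H <= 0 || kdeg_G <= 0) stop("kdeg must be > 0")
  if (Enz_0_H < 0 || Enz_0_G < 0) stop("enzyme amounts must be >= 0")
  structure(list(kdeg_H = kdeg_H, kdeg_G = kdeg_G,
                 Enz_0_H = Enz_0_H, Enz_0_G = Enz_0_G),
            class = "enzyme_settings")
}

#' Elimination pathway of a compound
#'
#' Either a linear unbound intrinsic clearance (whole-organ L/h) or
#' Michaelis-Menten kinetics (`Vmax` mg/h whole organ, `Km_u` unbound uM).
#'
#' @param enzyme `"CYP3A4"` (scales with the active enzyme pool) or
#'   `"other"` / `"additional_HLM"` (fixed).
#' @param site `"liver"` or `"gut"`.
#' @param CLu_int linear unbound intrinsic clearance (L/h), or `NULL`.
#' @param Vmax,Km_u Michaelis-Menten alternative; exactly one mode must be
#'   given.
#' @return object of class `pathway_clearance`.
#' @export
pathway_clearance <- function(enzyme, site = c("liver", "gut"),
                              CLu_int = NULL, Vmax = NULL, Km_u = NULL) {
  site <- match.arg(site)
  enzyme <- as.character(enzyme)
  if (!toupper(enzyme) %in% c("CYP3A4", "OTHER", "ADDITIONAL_HLM", "ADDITIONAL-HLM"))
    stop("unknown enzyme name: ", enzyme)
  has_lin <- !is.null(CLu_int)
  has_mm <- !is.null(Vmax) || !is.null(Km_u)
  if (has_lin == has_mm)
    stop("exactly one of CLu_int or (Vmax, Km_u) must be given")
  if (has_mm) {
    if (is.null(Vmax) || is.null(Km_u)) stop("Vmax and Km_u are both required")
    if (Km_u <= 0) stop("Km_u must be > 0")
    if (Vmax < 0) stop("Vmax must be >= 0")
  } else if (CLu_int < 0) stop("CLu_int must be >= 0")
  structure(list(enzyme = enzyme, site = site,
                 mode = if (has_lin) "clint" else "michaelis_menten",
                 CLu_int = CLu_int, Vmax = Vmax, Km_u = Km_u),
            class = "pathway_clearance")
}

#' Compound parameter profile
#'
#' All victim/perpetrator parameters of the minimal-PBPK model.
#' Interaction terms (`IndC_50`, `Ki_u`, `K_I`) are unbound uM and are
#' evaluated from the internal mg/L state via the molecular weight.
#'
#' @param name compound name.
#' @param MW molecular weight (g/mol).
#' @param fu_p unbound fraction in plasma (0, 1].
#' @param BP blood:plasma concentration ratio.
#' @param fu_gut unbound fraction in the enterocyte (0, 1].
#' @param Kp_liver liver:plasma partition coefficient.
#' @param ka first-order absorption rate constant (1/h).
#' @param Fa fraction absorbed from the lumen \[0, 1\].
#' @param Vss steady-state volume of distribution (L/kg).
#' @param CL_renal renal (plasma) clearance, L/h.
#' @param elimination list of [pathway_clearance()] entries.
#' @param inhibition named numeric of unbound competitive inhibition
#'   constants, e.g. `c(CYP3A4 = 18)` (uM); `NULL` for none.
#' @param mbi optional mechanism-based inactivation,
#'   `list(K_I = uM, k_inact = 1/h)`.
#' @param induction optional CYP3A4 induction parameters:
#'   `list(liver = c(Ind_max, IndC_50), gut = c(Ind_max, IndC_50))`, or a
#'   single `c(Ind_max, IndC_50)` applied to both sites.
#' @return object of class `compound_profile`.
#' @export
compound_profile <- function(name, MW, fu_p, BP = 1, fu_gut = 1,
                             Kp_liver = 1, ka = 1, Fa = 1, Vss = 0.7,
                             CL_renal = 0, elimination = list(),
                             inhibition = NULL, mbi = NULL,
                             induction = NULL) {
  if (fu_p <= 0 || fu_p > 1) stop("fu_p must be in (0, 1]")
  if (fu_gut <= 0 || fu_gut > 1) stop("fu_gut must be in (0, 1]")
  if (BP <= 0) stop("BP must be > 0")
  if (ka < 0) stop("ka must be >= 0")
  if (Fa < 0 || Fa > 1) stop("Fa must be in [0, 1]")
  if (Vss <= 0) stop("Vss must be > 0")
  if (CL_renal < 0) stop("CL_renal must be >= 0")
  if (Kp_liver <= 0) stop("Kp_liver must be > 0")
  if (MW <= 0) stop("MW must be > 0")
  stopifnot(all(vapply(elimination, inherits, logical(1), "pathway_clearance")))
  if (!is.null(inhibition)) {
    if (is.null(names(inhibition)) || any(!nzchar(names(inhibition))))
      stop("inhibition must be a named numeric (enzyme -> Ki_u)")
    bad <- setdiff(toupper(names(inhibition)), "CYP3A4")
    if (length(bad)) stop("unknown enzyme name in inhibition: ",
                          paste(bad, collapse = ", "))
    if (any(inhibition <= 0)) stop("Ki_u must be > 0")
  }
  if (!is.null(mbi)) {
    if (is.null(mbi$K_I) || is.null(mbi$k_inact))
      stop("mbi requires K_I and k_inact")
    if (mbi$K_I <= 0 || mbi$k_inact < 0) stop("invalid mbi parameters")
  }
  if (!is.null(induction)) induction <- .norm_induction(induction)
  structure(list(name = as.character(name), MW = MW, fu_p = fu_p, BP = BP,
                 fu_gut = fu_gut, Kp_liver = Kp_liver, ka = ka, Fa = Fa,
                 Vss = Vss, CL_renal = CL_renal, elimination = elimination,
                 inhibition = inhibition, mbi = mbi, induction = induction),
            class = "compound_profile")
}

.norm_induction <- function(induction) {
  if (is.numeric(induction)) induction <- list(liver = induction, gut = induction)
  for (s in c("liver", "gut")) {
    v <- induction[[s]]
    if (is.null(v)) v <- c(Ind_max = 1, IndC_50 = 1)
    v <- unname(as.numeric(v))
    if (length(v) != 2 || v[1] < 1 || v[2] <= 0)
      stop("induction parameters must be c(Ind_max >= 1, IndC_50 > 0)")
    induction[[s]] <- c(Ind_max = v[1], IndC_50 = v[2])
  }
  induction[c("liver", "gut")]
}

#' Set site-specific induction parameters on a profile
#'
#' @param profile a [compound_profile()].
#' @param params a [reference_set()] result, a `calibrated_induction`, or
#'   a `list(liver = c(Ind_max, IndC_50), gut = ...)`.
#' @return the modified profile.
#' @export
set_induction <- function(profile, params) {
  stopifnot(inherits(profile, "compound_profile"))
  if (inherits(params, "calibrated_induction"))
    params <- c(params$Ind_max_cal, params$IndC_50_cal)
  if (is.list(params) && !is.null(params$liver))
    params <- list(liver = params$liver, gut = params$gut)
  profile$induction <- .norm_induction(params)
  profile
}

#' @export
print.compound_profile <- function(x, ...) {
  cl <- .flatten_clearances(x)
  cat(sprintf(
    "<compound_profile> %s: MW %.4g, fu_p %.3g, B:P %.3g, fu_gut %.3g, ka %.3g/h, Fa %.3g, Vss %.3g L/kg\n",
    x$name, x$MW, x$fu_p, x$BP, x$fu_gut, x$ka, x$Fa, x$Vss))
  cat(sprintf("  CLu_int (L/h): liver 3A4 %.4g / other %.4g; gut 3A4 %.4g / other %.4g; CL_renal %.3g\n",
              cl$CLuH_3A4, cl$CLuH_other, cl$CLuG_3A4, cl$CLuG_other, x$CL_renal))
  if (!is.null(x$induction))
    cat(sprintf("  induction: liver (%.4g, %.3g uM), gut (%.4g, %.3g uM)\n",
                x$induction$liver[1], x$induction$liver[2],
                x$induction$gut[1], x$induction$gut[2]))
  invisible(x)
}

# collapse the pathway list onto the four (site x CYP3A4/other) slots used
# by the ODE core; Michaelis-Menten pathways carry CLu = Vmax/Km on the
# unbound mg/L scale (exact MM via the shared saturation denominator)
.flatten_clearances <- function(profile) {
  sl <- list(CLuH_3A4 = 0, KmH_3A4 = Inf, CLuH_other = 0, KmH_other = Inf,
             CLuG_3A4 = 0, KmG_3A4 = Inf, CLuG_other = 0, KmG_other = Inf)
  for (p in profile$elimination) {
    is3a4 <- toupper(p$enzyme) == "CYP3A4"
    key <- paste0(if (p$site == "liver") "CLuH" else "CLuG",
                  if (is3a4) "_3A4" else "_other")
    kmkey <- sub("CLu", "Km", key)
    if (p$mode == "clint") {
      sl[[key]] <- sl[[key]] + p$CLu_int
    } else {
      if (sl[[key]] > 0)
        stop("at most one pathway (and no mixing with linear CLu_int) is ",
             "supported per site/enzyme slot when using Michaelis-Menten kinetics")
      sl[[key]] <- p$Vmax * 1000 / (p$Km_u * profile$MW)
      sl[[kmkey]] <- p$Km_u
    }
  }
  sl
}

#' Enzyme turnover derivative (liver and gut CYP3A4 pools)
#'
#' Right-hand side of the enzyme amount equations: zero-order synthesis
#' stimulated by induction, first-order degradation, and optional
#' mechanism-based inactivation:
#' `dEnz/dt = kdeg * Enz_0 * (1 + (Ind_max - 1) * I / (IndC_50 + I))
#'   - kdeg * Enz_act - Enz_act * k_inact * I / (K_I + I)`.
#'
#' @param state list with `Enz_act_H`, `Enz_act_G` and optionally
#'   `Enz_0_H`, `Enz_0_G` (default 1), `kdeg_H`, `kdeg_G` (default
#'   [enzyme_settings()] values).
#' @param I_liver_u unbound perpetrator concentration driving the liver
#'   pool (uM, >= 0).
#' @param I_gut_u unbound perpetrator concentration driving the gut pool
#'   (uM, >= 0).
#' @param induction `list(liver = c(Ind_max, IndC_50), gut = ...)` or a
#'   single pair for both sites.
#' @param mbi optional `list(K_I, k_inact)`.
#' @return named numeric `c(dEnz_H, dEnz_G)` (1/h).
#' @export
enzyme_rhs <- function(state, I_liver_u, I_gut_u, induction, mbi = NULL) {
  if (I_liver_u < 0 || I_gut_u < 0)
    stop("perpetrator concentrations must be >= 0")
  induction <- .norm_induction(induction)
  d <- enzyme_settings()
  kH <- state$kdeg_H %||% d$kdeg_H
  kG <- state$kdeg_G %||% d$kdeg_G
  e0H <- state$Enz_0_H %||% 1
  e0G <- state$Enz_0_G %||% 1
  stim <- function(pars, I) (pars[["Ind_max"]] - 1) * I / (pars[["IndC_50"]] + I)
  inact <- function(I) if (is.null(mbi)) 0 else
    mbi$k_inact * I / (mbi$K_I + I)
  dH <- kH * e0H * (1 + stim(induction$liver, I_liver_u)) -
    kH * state$Enz_act_H - state$Enz_act_H * inact(I_liver_u)
  dG <- kG * e0G * (1 + stim(induction$gut, I_gut_u)) -
    kG * state$Enz_act_G - state$Enz_act_G * inact(I_gut_u)
  c(dEnz_H = dH, dEnz_G = dG)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Perpetrator-modified intrinsic clearances of a victim
#'
#' Per-pathway unbound intrinsic clearance in the presence of a
#' perpetrator: each CYP3A4 pathway scales with the active enzyme fold and
#' is divided by the competitive-inhibition term `1 + I_u / Ki_u`;
#' non-CYP3A4 pathways are unchanged. Michaelis-Menten pathways are
#' additionally saturated by the victim's own unbound concentration.
#'
#' @param victim a [compound_profile()].
#' @param enzymes active enzyme folds `c(liver = , gut = )` relative to
#'   baseline.
#' @param I_liver_u,I_pv_u unbound perpetrator concentrations (uM) in the
#'   liver (liver pathways) and portal vein (gut pathways).
#' @param perpetrator optional [compound_profile()] supplying `Ki_u`; with
#'   no perpetrator or no `Ki_u` the inhibition divisor is 1.
#' @param S_liver_u,S_gut_u unbound victim concentrations (uM) for
#'   Michaelis-Menten saturation (default 0: linear range).
#' @return list with `CLu_int_H`, `CLu_int_G` (L/h), their CYP3A4/other
#'   components, and `fm_CYP3A4_H`, the hepatic CYP3A4 fraction at this
#'   state.
#' @export
clearance_terms <- function(victim, enzymes = c(liver = 1, gut = 1),
                            I_liver_u = 0, I_pv_u = 0, perpetrator = NULL,
                            S_liver_u = 0, S_gut_u = 0) {
  stopifnot(inherits(victim, "compound_profile"))
  sl <- .flatten_clearances(victim)
  ki <- Inf
  if (!is.null(perpetrator) && !is.null(perpetrator$inhibition))
    ki <- unname(perpetrator$inhibition[["CYP3A4"]] %||% Inf)
  divH <- 1 + I_liver_u / ki
  divG <- 1 + I_pv_u / ki
  h3 <- enzymes[["liver"]] * sl$CLuH_3A4 / ((1 + S_liver_u / sl$KmH_3A4) * divH)
  ho <- sl$CLuH_other / (1 + S_liver_u / sl$KmH_other)
  g3 <- enzymes[["gut"]] * sl$CLuG_3A4 / ((1 + S_gut_u / sl$KmG_3A4) * divG)
  go <- sl$CLuG_other / (1 + S_gut_u / sl$KmG_other)
  tot_h <- h3 + ho
  list(CLu_int_H = tot_h, CLu_int_G = g3 + go,
       CLuH_3A4 = h3, CLuH_other = ho, CLuG_3A4 = g3, CLuG_other = go,
       fm_CYP3A4_H = if (tot_h > 0) h3 / tot_h else NA_real_)
}

#' Dosing regimen
#'
#' @param compound compound name (must match a simulated profile).
#' @param dose dose per administration (mg, or mg/kg when
#'   `dose_per_kg = TRUE`).
#' @param route `"oral"`, `"iv_bolus"` or `"iv_infusion"`.
#' @param n_doses number of administrations.
#' @param interval dosing interval (h); required when `n_doses > 1`.
#' @param start_time time of the first dose (h).
#' @param dose_per_kg logical; resolve the dose with body weight.
#' @param inf_duration infusion duration (h) for `"iv_infusion"`
#'   (approximated internally by a train of small boluses).
#' @return object of class `dose_regimen`.
#' @export
dose_regimen <- function(compound, dose, route = c("oral", "iv_bolus", "iv_infusion"),
                         n_doses = 1, interval = 24, start_time = 0,
                         dose_per_kg = FALSE, inf_duration = 0.5) {
  route <- match.arg(route)
  if (dose <= 0) stop("dose must be > 0")
  if (n_doses < 1) stop("n_doses must be >= 1")
  if (n_doses > 1 && interval <= 0) stop("interval must be > 0 for repeated dosing")
  structure(list(compound = as.character(compound), dose = dose, route = route,
                 n_doses = as.integer(n_doses), interval = interval,
                 start_time = start_time, dose_per_kg = isTRUE(dose_per_kg),
                 inf_duration = inf_duration),
            class = "dose_regimen")
}

.state_names <- function() {
  s <- c("A_lumen", "A_ent", "A_pv", "A_liv", "A_sys", "cum_abs", "cum_gut",
         "cum_metH3A4", "cum_metHoth", "cum_metG", "cum_renal", "cum_auc")
  c(paste0("V.", s), paste0("P.", s), "EnzH", "EnzG")
}

.inert_profile <- function() {
  compound_profile("none", MW = 300, fu_p = 1, BP = 1, Vss = 0.7)
}

.compound_parms <- function(profile, system) {
  sl <- .flatten_clearances(profile)
  ki <- Inf
  if (!is.null(profile$inhibition))
    ki <- unname(profile$inhibition[["CYP3A4"]] %||% Inf)
  ind <- profile$induction %||% list(liver = c(Ind_max = 1, IndC_50 = 1),
                                     gut = c(Ind_max = 1, IndC_50 = 1))
  mbi <- profile$mbi %||% list(K_I = Inf, k_inact = 0)
  c(profile$MW, profile$fu_p, profile$BP, profile$fu_gut, profile$ka,
    profile$Vss * system$body_weight, profile$CL_renal, profile$Kp_liver,
    sl$CLuH_3A4, sl$KmH_3A4, sl$CLuH_other, sl$KmH_other,
    sl$CLuG_3A4, sl$KmG_3A4, sl$CLuG_other, sl$KmG_other,
    ki, ind$liver[["Ind_max"]], ind$liver[["IndC_50"]],
    ind$gut[["Ind_max"]], ind$gut[["IndC_50"]],
    mbi$K_I, mbi$k_inact)
}

.pbpk_parms <- function(victim, perpetrator, system, enzyme, clamp = NULL) {
  cl <- c(0, 0, 0)
  if (!is.null(clamp)) cl <- c(1, clamp$I_liver_u, clamp$I_gut_u)
  c(system$Q_h, system$Q_pv, system$Q_gut, system$V_ent, system$V_pv,
    system$V_liver, enzyme$kdeg_H, enzyme$kdeg_G, cl,
    .compound_parms(victim, system),
    .compound_parms(perpetrator %||% .inert_profile(), system))
}

# baseline plasma clearance and half-life used for horizon selection
.base_cl_plasma <- function(profile, system) {
  sl <- .flatten_clearances(profile)
  fuB <- profile$fu_p / profile$BP
  cluH <- sl$CLuH_3A4 + sl$CLuH_other
  clh_b <- system$Q_h * fuB * cluH / (system$Q_h + fuB * cluH)
  clh_b * profile$BP + profile$CL_renal
}

.base_thalf <- function(profile, system) {
  cl <- .base_cl_plasma(profile, system)
  if (cl <= 1e-9) return(48)
  log(2) * profile$Vss * system$body_weight / cl
}

.dose_events <- function(regimen, prefix, bw) {
  amt <- regimen$dose * if (regimen$dose_per_kg) bw else 1
  tms <- regimen$start_time + (seq_len(regimen$n_doses) - 1) * regimen$interval
  if (regimen$route == "oral") {
    data.frame(var = paste0(prefix, ".A_lumen"), time = tms,
               value = amt, stringsAsFactors = FALSE)
  } else if (regimen$route == "iv_bolus") {
    data.frame(var = paste0(prefix, ".A_sys"), time = tms,
               value = amt, stringsAsFactors = FALSE)
  } else { # iv_infusion as a train of mini-boluses across the duration
    k <- max(4L, ceiling(regimen$inf_duration * 4))
    off <- (seq_len(k) - 0.5) * regimen$inf_duration / k
    data.frame(var = paste0(prefix, ".A_sys"),
               time = rep(tms, each = k) + rep(off, length(tms)),
               value = amt / k, stringsAsFactors = FALSE)
  }
}

#' Simulation options
#'
#' @param rtol,atol relative/absolute solver tolerances.
#' @param method deSolve integration method.
#' @param out_dt output grid spacing (h); default adapts to the horizon.
#' @param horizon simulation end time (h); default: last dose plus five
#'   victim half-lives (at least 24 h).
#' @param maxsteps maximum internal solver steps.
#' @return list of options.
#' @export
sim_options <- function(rtol = 1e-7, atol = 1e-8, method = "lsoda",
                        out_dt = NULL, horizon = NULL, maxsteps = 100000) {
  list(rtol = rtol, atol = atol, method = method, out_dt = out_dt,
       horizon = horizon, maxsteps = maxsteps)
}

#' Simulate victim/perpetrator kinetics with dynamic CYP3A4 pools
#'
#' Integrates the minimal-PBPK model for a victim and (optionally) a
#' perpetrator, with the active CYP3A4 amounts in liver and gut following
#' enzyme-turnover dynamics driven by the perpetrator's unbound liver and
#' enterocyte concentrations. Dosing is handled by state re-initialisation
#' at the event times. Autoinduction emerges naturally when a compound
#' both induces and is eliminated by CYP3A4.
#'
#' @param victim a [compound_profile()].
#' @param regimens a [dose_regimen()] or list of them; regimen `compound`
#'   names must match the profile names.
#' @param perpetrator optional [compound_profile()].
#' @param system [system_parameters()].
#' @param enzyme [enzyme_settings()].
#' @param options [sim_options()].
#' @param clamp optional `list(I_liver_u =, I_gut_u =, equilibrate = TRUE)`:
#'   hold the perpetrator driving concentrations constant (unbound uM) and,
#'   if `equilibrate`, start the enzyme pools at their analytic steady
#'   state for those concentrations.
#' @param init_enzyme initial relative enzyme amounts `c(liver, gut)`.
#' @return object of class `ddi_sim`: the solver output (`$out`), per-
#'   compound metric lists (`$victim`, `$perpetrator`) with `AUC_0_t`,
#'   `AUC_0_inf`, `C_max`, `F_G`, `F_H`, `fm_CYP3A4`, and enzyme
#'   trajectory summaries.
#' @export
simulate_ddi <- function(victim, regimens, perpetrator = NULL,
                         system = system_parameters(),
                         enzyme = enzyme_settings(),
                         options = sim_options(), clamp = NULL,
                         init_enzyme = c(1, 1)) {
  stopifnot(inherits(victim, "compound_profile"))
  if (inherits(regimens, "dose_regimen")) regimens <- list(regimens)
  stopifnot(all(vapply(regimens, inherits, logical(1), "dose_regimen")))

  roles <- c(victim$name, if (!is.null(perpetrator)) perpetrator$name)
  for (r in regimens)
    if (!r$compound %in% roles)
      stop("regimen compound '", r$compound, "' matches no simulated profile")

  bw <- system$body_weight
  ev <- do.call(rbind, lapply(regimens, function(r) {
    pre <- if (r$compound == victim$name) "V" else "P"
    d <- .dose_events(r, pre, bw)
    if (pre == "V" && r$route == "oral") d$value <- d$value * victim$Fa
    if (pre == "P" && r$route == "oral") d$value <- d$value * perpetrator$Fa
    d
  }))
  ev$method <- "add"
  ev$time <- round(ev$time, 6)
  ev <- ev[order(ev$time), ]

  vic_regs <- Filter(function(r) r$compound == victim$name, regimens)
  if (length(vic_regs) == 0) stop("no regimen doses the victim")
  vic_last <- max(vapply(vic_regs, function(r)
    r$start_time + (r$n_doses - 1) * r$interval, numeric(1)))
  vic_first <- min(vapply(vic_regs, `[[`, numeric(1), "start_time"))
  t_half <- .base_thalf(victim, system)
  horizon <- options$horizon %||% max(max(ev$time) + 1,
                                      vic_last + max(24, 5 * t_half))

  dt <- options$out_dt %||% max(0.25, horizon / 600)
  times <- seq(0, horizon, by = dt)
  fine <- vic_first + seq(0, min(24, horizon - vic_first), by = 0.25)
  times <- sort(unique(round(c(times, ev$time, fine, horizon), 6)))
  times <- times[times <= horizon + 1e-9]

  if (!is.null(clamp) && isTRUE(clamp$equilibrate %||% TRUE) &&
      !is.null(perpetrator)) {
    ind <- perpetrator$induction %||% list(liver = c(Ind_max = 1, IndC_50 = 1),
                                           gut = c(Ind_max = 1, IndC_50 = 1))
    mbi <- perpetrator$mbi
    ssf <- function(pars, I, kdeg) {
      stim <- 1 + (pars[["Ind_max"]] - 1) * I / (pars[["IndC_50"]] + I)
      loss <- kdeg + if (is.null(mbi)) 0 else mbi$k_inact * I / (mbi$K_I + I)
      kdeg * stim / loss
    }
    init_enzyme <- c(ssf(ind$liver, clamp$I_liver_u, enzyme$kdeg_H),
                     ssf(ind$gut, clamp$I_gut_u, enzyme$kdeg_G))
  }

  y <- setNames(numeric(26), .state_names())
  y["EnzH"] <- init_enzyme[1]
  y["EnzG"] <- init_enzyme[2]

  parms <- .pbpk_parms(victim, perpetrator, system, enzyme, clamp)
  out <- deSolve::ode(y = y, times = times, func = "pbpk_derivs",
                      parms = parms, dllname = "cypind",
                      initfunc = "pbpk_initmod",
                      events = list(data = ev), method = options$method,
                      rtol = options$rtol, atol = options$atol,
                      maxsteps = options$maxsteps)
  if (attr(out, "istate")[1] < 0)
    stop("ODE integration failed (istate ", attr(out, "istate")[1], ")")
  out <- as.data.frame(out)
  if (min(out[, -1], na.rm = TRUE) < -1e-4 * max(abs(out[, -1])))
    stop("integration produced substantially negative states")

  res <- structure(
    list(out = out, victim_name = victim$name,
         perpetrator_name = perpetrator$name %||% NULL,
         system = system, enzyme = enzyme, regimens = regimens,
         profiles = list(victim = victim, perpetrator = perpetrator)),
    class = "ddi_sim")
  res$victim <- .compound_metrics(res, "V", victim, vic_first)
  if (!is.null(perpetrator)) {
    per_regs <- Filter(function(r) r$compound == perpetrator$name, regimens)
    pf <- if (length(per_regs)) min(vapply(per_regs, `[[`, numeric(1),
                                           "start_time")) else 0
    res$perpetrator <- .compound_metrics(res, "P", perpetrator, pf)
  }
  res
}

#' @export
print.ddi_sim <- function(x, ...) {
  cat(sprintf("<ddi_sim> victim %s%s, %d time points, horizon %.4g h\n",
              x$victim_name,
              if (!is.null(x$perpetrator_name))
                paste0(" + perpetrator ", x$perpetrator_name) else "",
              nrow(x$out), max(x$out$time)))
  cat(sprintf("  victim AUC_0_inf %.5g mg/L.h, Cmax %.4g mg/L, F_G %.3g, F_H %.3g, fm_CYP3A4 %.3g\n",
              x$victim$AUC_0_inf, x$victim$C_max, x$victim$F_G, x$victim$F_H,
              x$victim$fm_CYP3A4))
  invisible(x)
}

.compound_metrics <- function(res, prefix, profile, t_first_dose) {
  out <- res$out
  col <- function(nm) out[[paste0(prefix, ".", nm)]]
  vsys <- profile$Vss * res$system$body_weight
  conc <- pmax(col("A_sys") / vsys, 0)
  tt <- out$time
  sel <- tt >= t_first_dose - 1e-9
  i0 <- which(sel)[1]
  auc_state <- col("cum_auc")
  auc_0_t <- auc_state[length(auc_state)] - auc_state[i0]

  term <- .terminal_slope(tt[sel], conc[sel])
  auc_inf <- if (is.na(term$lambda_z)) NA_real_ else
    auc_0_t + conc[length(conc)] / term$lambda_z

  abs_tot <- col("cum_abs")[length(tt)] - col("cum_abs")[i0]
  gut_esc <- col("cum_gut")[length(tt)] - col("cum_gut")[i0]
  mh3 <- col("cum_metH3A4")[length(tt)]
  mho <- col("cum_metHoth")[length(tt)]
  ren <- col("cum_renal")[length(tt)]
  elim <- mh3 + mho + ren

  sl <- .flatten_clearances(profile)
  fuB <- profile$fu_p / profile$BP
  cluH <- sl$CLuH_3A4 + sl$CLuH_other
  F_H <- res$system$Q_h / (res$system$Q_h + fuB * cluH)

  list(AUC_0_t = auc_0_t, AUC_0_inf = auc_inf, lambda_z = term$lambda_z,
       auc_flagged = is.na(term$lambda_z),
       C_max = max(conc[sel]),
       F_G = if (abs_tot > 1e-9) gut_esc / abs_tot else NA_real_,
       F_H = F_H,
       fm_CYP3A4 = if (elim > 1e-12) mh3 / elim else NA_real_,
       enz_H_max = max(out$EnzH), enz_G_max = max(out$EnzG),
       t_first_dose = t_first_dose)
}

# log-linear terminal slope on the tail of a concentration profile
.terminal_slope <- function(time, conc, n_tail = 6) {
  keep <- which(conc > 0)
  if (length(keep) < 3) return(list(lambda_z = NA_real_, r2 = NA_real_))
  imax <- keep[which.max(conc[keep])]
  cand <- keep[keep > imax]
  if (length(cand) < 3) return(list(lambda_z = NA_real_, r2 = NA_real_))
  idx <- tail(cand, n_tail)
  ft <- lm(log(conc[idx]) ~ time[idx])
  sl <- unname(coef(ft)[2])
  if (!is.finite(sl) || sl >= -1e-10)
    return(list(lambda_z = NA_real_, r2 = NA_real_))
  r2 <- suppressWarnings(summary(ft)$r.squared)
  if (is.finite(r2) && r2 < 0.8)
    return(list(lambda_z = NA_real_, r2 = r2))
  list(lambda_z = -sl, r2 = r2)
}

#' Non-compartmental metrics from a concentration profile
#'
#' Trapezoidal AUC over an interval plus a `C_last / lambda_z`
#' extrapolation from the terminal log-linear phase. When no reliable
#' terminal slope is identifiable, `AUC_0_inf` is `NA` and flagged, with
#' the truncated AUC still returned.
#'
#' @param time,conc numeric vectors (h, mg/L or compatible).
#' @param interval optional `c(from, to)` restriction (h).
#' @return list with `AUC_0_t`, `AUC_0_inf`, `C_max`, `t_max`, `lambda_z`,
#'   `flagged`.
#' @export
extract_metrics <- function(time, conc, interval = NULL) {
  stopifnot(length(time) == length(conc), length(time) >= 2)
  if (!is.null(interval)) {
    sel <- time >= interval[1] - 1e-9 & time <= interval[2] + 1e-9
    time <- time[sel]; conc <- conc[sel]
  }
  if (length(time) < 2) stop("profile does not cover the requested interval")
  auc <- sum(diff(time) * (head(conc, -1) + tail(conc, -1)) / 2)
  term <- .terminal_slope(time, conc)
  auc_inf <- if (is.na(term$lambda_z)) NA_real_ else
    auc + conc[length(conc)] / term$lambda_z
  list(AUC_0_t = auc, AUC_0_inf = auc_inf, C_max = max(conc),
       t_max = time[which.max(conc)], lambda_z = term$lambda_z,
       flagged = is.na(term$lambda_z))
}

#' Mechanistic static net-effect AUC ratios
#'
#' Closed-form control/induced AUC ratios built from constant enzyme
#' fold-changes, using the well-stirred liver and the gut extraction
#' model: `F_H = Q_h / (Q_h + fu_B * CLu_int_H)`,
#' `F_G = Q_gut / (Q_gut + fu_gut * CLu_int_G)`,
#' oral ratio `= (F_G F_H / CL)_control / (F_G F_H / CL)_induced`,
#' i.v. ratio `= CL_induced / CL_control`. Serves as the static
#' counterpart of the dynamic model for equivalence checks.
#'
#' @param victim a [compound_profile()].
#' @param system [system_parameters()].
#' @param enz_fold enzyme folds `c(liver =, gut =)` in the induced state.
#' @param div_H,div_G competitive-inhibition divisors for liver and gut
#'   CYP3A4 pathways in the induced state (default 1).
#' @return list with `oral_ratio`, `iv_ratio` and the underlying
#'   `F_G`/`F_H`/`CL` values for both states.
#' @export
static_net_effect <- function(victim, system = system_parameters(),
                              enz_fold = c(liver = 1, gut = 1),
                              div_H = 1, div_G = 1) {
  stopifnot(inherits(victim, "compound_profile"))
  fuB <- victim$fu_p / victim$BP
  one <- function(foldH, foldG, dH, dG) {
    ct <- clearance_terms(victim, enzymes = c(liver = 1, gut = 1))
    cluH <- ct$CLuH_3A4 * foldH / dH + ct$CLuH_other
    cluG <- ct$CLuG_3A4 * foldG / dG + ct$CLuG_other
    F_H <- system$Q_h / (system$Q_h + fuB * cluH)
    F_G <- system$Q_gut / (system$Q_gut + victim$fu_gut * cluG)
    CL <- system$Q_h * fuB * cluH / (system$Q_h + fuB * cluH) * victim$BP +
      victim$CL_renal
    list(F_H = F_H, F_G = F_G, CL = CL)
  }
  ctl <- one(1, 1, 1, 1)
  ind <- one(enz_fold[["liver"]], enz_fold[["gut"]], div_H, div_G)
  list(oral_ratio = (ctl$F_G * ctl$F_H / ctl$CL) /
         (ind$F_G * ind$F_H / ind$CL),
       iv_ratio = ind$CL / ctl$CL,
       control = ctl, induced = ind)
}
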