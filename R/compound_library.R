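# Curated example compound profiles.
#
# Victim profiles are constructed from design targets (hepatic extraction
# E_H, fraction escaping gut metabolism F_G, hepatic CYP3A4 fraction fm)
# that are representative of the published clinical pharmacology of each
# probe substrate; the intrinsic clearances are back-calculated from those
# targets against the default system parameters. They are curated example
# profiles, not transcriptions of any proprietary compound database.

.victim_targets <- list(
  #            MW    fu_p  BP   fugut Kp  ka  Fa   Vss  EH   FG   fm
  midazolam  = c(325.8, 0.032, 0.66, 1, 3.0, 3.0, 1.00, 1.00, 0.44, 0.51, 0.92),
  alfentanil = c(416.5, 0.080, 0.63, 1, 1.5, 6.0, 1.00, 0.75, 0.35, 0.85, 0.90),
  nifedipine = c(346.3, 0.040, 0.68, 1, 2.0, 1.5, 1.00, 0.80, 0.50, 0.75, 0.80),
  simvastatin = c(418.6, 0.020, 0.60, 1, 3.0, 1.0, 0.85, 1.00, 0.70, 0.50, 0.85),
  alprazolam = c(308.8, 0.290, 0.78, 1, 1.0, 1.5, 0.90, 0.75, 0.04, 0.94, 0.80),
  zolpidem   = c(307.4, 0.080, 0.76, 1, 1.5, 2.0, 0.90, 0.70, 0.25, 0.79, 0.60),
  triazolam  = c(343.2, 0.100, 0.62, 1, 1.0, 2.5, 0.90, 1.00, 0.25, 0.60, 0.92),
  quinidine  = c(324.4, 0.130, 0.92, 1, 2.0, 1.5, 0.85, 2.70, 0.25, 0.90, 0.76))

#' Curated victim (CYP3A4 substrate) profiles
#'
#' Builds a [compound_profile()] for one of the bundled probe substrates.
#' Hepatic intrinsic clearances are derived from target hepatic extraction
#' and hepatic CYP3A4 fraction, and the gut CYP3A4 clearance from the
#' target fraction escaping gut metabolism, under the supplied system
#' parameters.
#'
#' @param name one of `"midazolam"`, `"alfentanil"`, `"nifedipine"`,
#'   `"simvastatin"`, `"alprazolam"`, `"zolpidem"`, `"triazolam"`,
#'   `"quinidine"` (three-letter clinical abbreviations MDZ/ALF/NIF/SMV/
#'   APZ/ZOL/TZM/QND also accepted).
#' @param system [system_parameters()] used for the back-calculation.
#' @return a [compound_profile()].
#' @export
victim_profile <- function(name, system = system_parameters()) {
  abbr <- c(MDZ = "midazolam", ALF = "alfentanil", NIF = "nifedipine",
            SMV = "simvastatin", APZ = "alprazolam", ZOL = "zolpidem",
            TZM = "triazolam", QND = "quinidine")
  key <- tolower(as.character(name))
  if (toupper(name) %in% names(abbr)) key <- abbr[[toupper(name)]]
  if (!key %in% names(.victim_targets)) stop("no curated victim profile: ", name)
  v <- .victim_targets[[key]]
  MW <- v[1]; fu_p <- v[2]; BP <- v[3]; fu_gut <- v[4]; Kp <- v[5]
  ka <- v[6]; Fa <- v[7]; Vss <- v[8]; EH <- v[9]; FG <- v[10]; fm <- v[11]
  fuB <- fu_p / BP
  cluH_tot <- system$Q_h * EH / (1 - EH) / fuB
  cluG_3a4 <- system$Q_gut * (1 - FG) / (FG * fu_gut)
  compound_profile(
    name = key, MW = MW, fu_p = fu_p, BP = BP, fu_gut = fu_gut,
    Kp_liver = Kp, ka = ka, Fa = Fa, Vss = Vss, CL_renal = 0,
    elimination = list(
      pathway_clearance("CYP3A4", "liver", CLu_int = fm * cluH_tot),
      pathway_clearance("other", "liver", CLu_int = (1 - fm) * cluH_tot),
      pathway_clearance("CYP3A4", "gut", CLu_int = cluG_3a4)))
}

#' Curated perpetrator (inducer) profiles
#'
#' `rifampicin` carries a fixed (non-CYP3A4) hepatic clearance, so no
#' autoinduction occurs, and site-specific induction parameters taken from
#' a [reference_set()] model (base model A by default).
#' `carbamazepine`, `phenytoin` and `phenobarbital` carry induction
#' parameters obtained by calibrating the bundled donor-mean in vitro
#' values (see [invitro_induction_table()]) against rifampicin from the
#' same assay and the requested in vivo reference; carbamazepine and
#' phenytoin are eliminated in part by CYP3A4 and therefore autoinduce.
#'
#' @param name `"rifampicin"`, `"carbamazepine"`, `"phenytoin"` or
#'   `"phenobarbital"`.
#' @param model [reference_set()] label for rifampicin (default
#'   `"model_A"`).
#' @param endpoint in vitro endpoint used for calibration of non-rifampicin
#'   inducers.
#' @param reference [in_vivo_reference()] used in that calibration
#'   (default the refined `Ind_max` 16 reference).
#' @param convention calibration convention, see [calibrate()].
#' @return a [compound_profile()].
#' @export
perpetrator_profile <- function(name, model = "model_A",
                                endpoint = c("activity", "mRNA"),
                                reference = in_vivo_reference(16, 0.32),
                                convention = "emax_scaling") {
  endpoint <- match.arg(endpoint)
  key <- tolower(as.character(name))
  if (key == "rifampicin") {
    rs <- reference_set(model)
    return(compound_profile(
      name = "rifampicin", MW = 822.9, fu_p = 0.15, BP = 0.9, fu_gut = 0.19,
      Kp_liver = 1, ka = 1.18, Fa = 0.96, Vss = 0.45, CL_renal = 0,
      elimination = list(pathway_clearance("other", "liver", CLu_int = 51.1)),
      induction = list(liver = rs$liver, gut = rs$gut)))
  }
  tab <- invitro_induction_table()
  row <- tab[tab$inducer == key & tab$endpoint == endpoint, ]
  if (nrow(row) != 1) stop("no curated perpetrator profile: ", name)
  rif <- tab[tab$inducer == "rifampicin" & tab$endpoint == endpoint, ]
  cal <- calibrate(
    test = list(Ind_max = row$Ind_max_mean, IndC_50 = row$IndC_50_mean,
                endpoint = endpoint),
    rif_same_assay = list(Ind_max = rif$Ind_max_mean,
                          IndC_50 = rif$IndC_50_mean, endpoint = endpoint),
    ref = reference, convention = convention)
  ind <- list(liver = c(Ind_max = cal$Ind_max_cal, IndC_50 = cal$IndC_50_cal),
              gut = c(Ind_max = cal$Ind_max_cal, IndC_50 = cal$IndC_50_cal))
  switch(key,
    carbamazepine = compound_profile(
      name = "carbamazepine", MW = 236.3, fu_p = 0.25, BP = 1.07, fu_gut = 1,
      Kp_liver = 1.2, ka = 0.5, Fa = 1, Vss = 1.0, CL_renal = 0,
      elimination = list(
        pathway_clearance("CYP3A4", "liver", CLu_int = 8),
        pathway_clearance("other", "liver", CLu_int = 4.4)),
      induction = ind),
    phenytoin = compound_profile(
      name = "phenytoin", MW = 252.3, fu_p = 0.10, BP = 0.70, fu_gut = 1,
      Kp_liver = 1, ka = 0.8, Fa = 0.9, Vss = 0.70, CL_renal = 0,
      elimination = list(
        pathway_clearance("CYP3A4", "liver", CLu_int = 6),
        pathway_clearance("other", "liver", CLu_int = 12)),
      induction = ind),
    phenobarbital = compound_profile(
      name = "phenobarbital", MW = 232.2, fu_p = 0.50, BP = 0.90, fu_gut = 1,
      Kp_liver = 1, ka = 0.5, Fa = 1, Vss = 0.70, CL_renal = 0.1,
      elimination = list(pathway_clearance("other", "liver", CLu_int = 0.55)),
      induction = ind),
    stop("no curated perpetrator profile: ", name))
}
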