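#' Read hepatocyte induction data from delimited text
#'
#' Expects a CSV with header columns `inducer`, `donor`, `endpoint`,
#' `conc_uM`, `fold` (extra column `replicate` optional). Malformed rows
#' (missing values, non-positive concentration or fold) are rejected with
#' a warning naming the offending line numbers; the remainder is loaded
#' and grouped by (inducer, donor, endpoint).
#'
#' @param path file path.
#' @return list of [induction_dataset()]s (empty, with a warning, for an
#'   empty file).
#' @export
read_induction_csv <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("inducer", "donor", "endpoint", "conc_uM", "fold")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("missing column(s): ", paste(miss, collapse = ", "))
  if (nrow(df) == 0) {
    warning("no data rows in ", path)
    return(list())
  }
  conc <- suppressWarnings(as.numeric(df$conc_uM))
  fold <- suppressWarnings(as.numeric(df$fold))
  bad <- !is.finite(conc) | conc <= 0 | !is.finite(fold) | fold <= 0 |
    is.na(df$inducer) | is.na(df$donor) |
    !df$endpoint %in% c("mRNA", "activity")
  if (any(bad)) {
    warning("rejected malformed row(s) at line(s): ",
            paste(which(bad) + 1L, collapse = ", "))
    df <- df[!bad, , drop = FALSE]
    conc <- conc[!bad]; fold <- fold[!bad]
  }
  if (nrow(df) == 0) return(list())
  rep_id <- if ("replicate" %in% names(df)) as.integer(df$replicate)
            else rep(1L, nrow(df))
  key <- paste(df$inducer, df$donor, df$endpoint, sep = "\r")
  lapply(split(seq_len(nrow(df)), key), function(ix) {
    induction_dataset(df$inducer[ix[1]], df$donor[ix[1]], df$endpoint[ix[1]],
                      conc[ix], fold[ix], rep_id[ix])
  })
}

#' Write induction datasets to CSV
#'
#' Inverse of [read_induction_csv()]; numeric values are written to full
#' double precision.
#'
#' @param datasets list of [induction_dataset()]s.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_induction_csv <- function(datasets, path) {
  rows <- do.call(rbind, lapply(datasets, function(d)
    data.frame(inducer = d$inducer, donor = d$donor_id, endpoint = d$endpoint,
               conc_uM = d$concentrations, fold = d$fold_response,
               replicate = d$replicate_id)))
  write.csv(rows, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a donor-summary table to CSV
#'
#' One row per (inducer, endpoint): donor means and standard deviations of
#' `Ind_max` and `IndC_50`.
#'
#' @param summaries list of [summarize_donors()] results (or a single one).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_donor_summary_csv <- function(summaries, path) {
  if (inherits(summaries, "donor_summary")) summaries <- list(summaries)
  rows <- do.call(rbind, lapply(summaries, function(s)
    data.frame(inducer = s$inducer, endpoint = s$endpoint,
               Ind_max_mean = s$mean_Ind_max, Ind_max_sd = s$sd_Ind_max,
               IndC_50_mean = s$mean_IndC_50, IndC_50_sd = s$sd_IndC_50,
               n_donors = s$n_donors)))
  write.csv(rows, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

.read_config <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "json") jsonlite::read_json(path, simplifyVector = TRUE)
  else if (ext %in% c("yaml", "yml")) yaml::read_yaml(path)
  else stop("unsupported config extension: .", ext, " (use .json or .yaml)")
}

.write_config <- function(x, path) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "json")
    jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                         null = "null", pretty = TRUE)
  else if (ext %in% c("yaml", "yml")) yaml::write_yaml(x, path, precision = 15)
  else stop("unsupported config extension: .", ext)
  invisible(path)
}

.profile_keys <- c("name", "MW", "fu_p", "BP", "fu_gut", "Kp_liver", "ka",
                   "Fa", "Vss", "CL_renal", "elimination", "inhibition",
                   "mbi", "induction")

#' Read a compound profile from JSON or YAML
#'
#' Strict schema: unknown keys raise an error, and all
#' [compound_profile()] invariants are enforced (errors name the
#' offending field). Elimination pathways are given as a list of objects
#' with `enzyme`, `site` and either `CLu_int` or `Vmax` + `Km_u`.
#'
#' @param path file path (`.json`, `.yaml`, `.yml`).
#' @return a [compound_profile()].
#' @export
read_compound_profile <- function(path) {
  x <- .read_config(path)
  unknown <- setdiff(names(x), .profile_keys)
  if (length(unknown))
    stop("unknown profile key(s): ", paste(unknown, collapse = ", "))
  if (!is.null(x$elimination)) {
    if (is.data.frame(x$elimination))
      x$elimination <- split(x$elimination, seq_len(nrow(x$elimination)))
    x$elimination <- lapply(x$elimination, function(p) {
      p <- as.list(p)
      pathway_clearance(p$enzyme, p$site,
                        CLu_int = if (!is.null(p$CLu_int) && !is.na(p$CLu_int))
                          p$CLu_int,
                        Vmax = if (!is.null(p$Vmax) && !is.na(p$Vmax)) p$Vmax,
                        Km_u = if (!is.null(p$Km_u) && !is.na(p$Km_u)) p$Km_u)
    })
  }
  if (!is.null(x$inhibition)) x$inhibition <- unlist(x$inhibition)
  if (!is.null(x$induction))
    x$induction <- lapply(x$induction, unlist)
  do.call(compound_profile, x)
}

#' Write a compound profile to JSON or YAML
#'
#' @param profile a [compound_profile()].
#' @param path output path (extension selects the format).
#' @return `path`, invisibly.
#' @export
write_compound_profile <- function(profile, path) {
  stopifnot(inherits(profile, "compound_profile"))
  x <- unclass(profile)
  x$elimination <- lapply(x$elimination, function(p)
    Filter(Negate(is.null), unclass(p)[c("enzyme", "site", "CLu_int",
                                         "Vmax", "Km_u")]))
  x$inhibition <- if (!is.null(x$inhibition)) as.list(x$inhibition)
  x$induction <- if (!is.null(x$induction)) lapply(x$induction, as.list)
  .write_config(Filter(Negate(is.null), x), path)
}

#' Read a DDI study design from JSON or YAML
#'
#' Schema: `study_id`, `perpetrator` and `victim` regimen objects
#' (`compound`, `dose`, `route`, optionally `interval`, `n_doses`,
#' `dose_per_kg`), `stagger`, `n_subjects`, `n_trials`, and an optional
#' `observed` object (`AUC_control`, `AUC_induced`, `ratio_printed`,
#' `n`, ...). Unknown keys raise an error.
#'
#' @param path file path.
#' @return a [ddi_study_design()].
#' @export
read_study_design <- function(path) {
  x <- .read_config(path)
  known <- c("study_id", "perpetrator", "victim", "stagger", "n_subjects",
             "n_trials", "age_range", "proportion_female", "observed",
             "ambiguous_stagger")
  unknown <- setdiff(names(x), known)
  if (length(unknown))
    stop("unknown design key(s): ", paste(unknown, collapse = ", "))
  reg <- function(r) dose_regimen(
    r$compound, r$dose, r$route, n_doses = r$n_doses %||% 1,
    interval = r$interval %||% 24, start_time = r$start_time %||% 0,
    dose_per_kg = r$dose_per_kg %||% FALSE)
  obs <- NULL
  if (!is.null(x$observed))
    obs <- observed_study(x$study_id, x$victim$compound, x$victim$route,
                          x$observed$n %||% x$n_subjects,
                          x$observed$AUC_control, x$observed$AUC_induced,
                          ratio_printed = x$observed$ratio_printed,
                          dose_escalated = x$observed$dose_escalated %||% FALSE)
  ddi_study_design(x$study_id, reg(x$perpetrator), reg(x$victim),
                   stagger = x$stagger %||% 0,
                   n_subjects = x$n_subjects %||% 10,
                   n_trials = x$n_trials %||% 10,
                   age_range = x$age_range %||% c(18, 55),
                   proportion_female = x$proportion_female %||% 0.5,
                   observed = obs,
                   ambiguous_stagger = x$ambiguous_stagger %||% FALSE)
}

#' Bundled clinical DDI study tables
#'
#' Raw transcriptions of the published study summaries shipped with the
#' package: 29 rifampicin studies (i.v. and oral victims) and 6 studies
#' of other inducers (carbamazepine, phenytoin, phenobarbital). AUC units
#' are as printed (ng/mL.h for the rifampicin set, mg/L.h otherwise).
#' `ratio_printed` is kept as a string so its printed precision is
#' available; `dose_escalated` marks studies whose printed ratio derives
#' from clearances rather than the AUC quotient, and `ratio_mismatch`
#' marks printed ratios that disagree with their rounded AUC quotient
#' (the printed value is authoritative).
#'
#' @param set `"rifampicin"`, `"other"`, or `"all"`.
#' @return data.frame of study records.
#' @export
ddi_study_table <- function(set = c("rifampicin", "other", "all")) {
  set <- match.arg(set)
  rd <- function(f) read.csv(
    system.file("extdata", f, package = "cypind", mustWork = TRUE),
    stringsAsFactors = FALSE, colClasses = c(ratio_printed = "character"))
  out <- switch(set,
    rifampicin = rd("rifampicin_ddi_studies.csv"),
    other = rd("other_inducer_ddi_studies.csv"),
    all = rbind(rd("rifampicin_ddi_studies.csv"),
                rd("other_inducer_ddi_studies.csv")))
  out
}

#' Load bundled study tables as simulation-ready designs
#'
#' Converts [ddi_study_table()] rows into [ddi_study_design()] objects
#' with attached [observed_study()] records. Ambiguous published staggers
#' are taken as simultaneous dosing and flagged in the design.
#'
#' @param set see [ddi_study_table()].
#' @param n_trials number of virtual trials per study (default 10).
#' @return named list of [ddi_study_design()]s.
#' @export
load_study_designs <- function(set = c("rifampicin", "other", "all"),
                               n_trials = 10) {
  tab <- ddi_study_table(set)
  out <- lapply(seq_len(nrow(tab)), function(i) {
    r <- tab[i, ]
    ddi_study_design(
      study_id = r$study_id,
      perpetrator_regimen = dose_regimen(r$perpetrator, r$perp_dose_mg,
                                         "oral", n_doses = r$perp_n_doses,
                                         interval = r$perp_interval_h),
      victim_regimen = dose_regimen(r$victim, r$victim_dose,
                                    route = r$route,
                                    dose_per_kg = r$dose_unit == "mg_per_kg"),
      stagger = r$stagger_h, n_subjects = r$n, n_trials = n_trials,
      observed = observed_study(r$study_id, r$victim, r$route, r$n,
                                r$auc_control, r$auc_induced,
                                ratio_printed = r$ratio_printed,
                                dose_escalated = r$dose_escalated,
                                auc_unit = r$auc_unit),
      ambiguous_stagger = r$stagger_ambiguous)
  })
  names(out) <- tab$study_id
  out
}

#' Write sweep results as tidy CSV
#'
#' @param sweep a [scenario_sweep()] result.
#' @param per_study_path,summary_path output paths (`NULL` to skip).
#' @return invisibly, the paths written.
#' @export
write_sweep_csv <- function(sweep, per_study_path = NULL, summary_path = NULL) {
  if (!is.null(per_study_path))
    write.csv(sweep$per_study, per_study_path, row.names = FALSE)
  if (!is.null(summary_path))
    write.csv(sweep$summary, summary_path, row.names = FALSE)
  invisible(c(per_study_path, summary_path))
}
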