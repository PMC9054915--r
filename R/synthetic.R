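#' Generate a synthetic "observed" concentration-time study
#'
#' Simulates each virtual subject with sampled physiology under a known
#' ("truth") compound record and multiplies every observation by a
#' multiplicative lognormal residual with the requested CV. The truth record
#' is retained so parameter-recovery analyses can score themselves. Stands
#' in for clinical raw data that are not publicly deposited.
#'
#' @param truth the `compound_record` the data are generated from.
#' @param regimens a `dose_regimen` or list of regimens for `truth`.
#' @param sampling_times observation times (h post first dose); the default
#'   rich grid matches rapid absorption and a long terminal phase.
#' @param residual_cv proportional residual CV (fraction, >= 0).
#' @param n number of subjects.
#' @param seed integer seed (population draw and residuals).
#' @param cv_map between-subject CVs; set all zero for a noise-free check.
#' @param t_end horizon; defaults past the last sampling time.
#' @param opts solver options.
#' @return object of class `synthetic_study`: `observations` (data.frame
#'   `subject`, `time_h`, `conc_ng_per_ml`), `truth`, `design`,
#'   `residual_cv`, `seed`.
#' @export
generate_profiles <- function(truth, regimens,
                              sampling_times = c(0.5, 1, 2, 3, 4, 6, 8, 12,
                                                 24, 48, 72),
                              residual_cv = 0.2, n = 10, seed = 1L,
                              cv_map = default_cv_map(), t_end = NULL,
                              opts = solver_options()) {
  stopifnot(residual_cv >= 0, n >= 1)
  if (inherits(regimens, "dose_regimen")) regimens <- list(regimens)
  if (is.null(t_end)) t_end <- max(sampling_times) + 1
  phys <- default_healthy_volunteer()
  pop <- sample_population(phys, n, variability_spec(cv_map, seed = seed))
  kpp <- scaled_kp_set(truth, phys)
  sdlog <- sqrt(log(1 + residual_cv^2))
  set.seed(seed + 1L)
  obs <- lapply(seq_len(n), function(i) {
    rec_i <- .apply_subject_multipliers(truth, pop[[i]])
    sim <- simulate_subject(list(rec_i), regimens, pop[[i]], t_end,
                            kpps = list(kpp), opts = opts)
    conc <- approx(sim$time, sim$plasma[, truth$name],
                   xout = sampling_times)$y
    eps <- if (sdlog > 0) exp(rnorm(length(conc), 0, sdlog)) else 1
    data.frame(subject = i, time_h = sampling_times, conc_ng_per_ml = conc * eps)
  })
  structure(list(observations = do.call(rbind, obs), truth = truth,
                 design = list(regimens = regimens,
                               sampling_times = sampling_times, n = n),
                 residual_cv = residual_cv, seed = as.integer(seed)),
            class = "synthetic_study")
}

#' Synthetic dose-escalation oral-clearance dataset
#'
#' Emulates a first-in-human escalation study: single-dose and day-8
#' steady-state CL/F per dose level generated from the truth record on the
#' mean subject, with optional multiplicative noise. With a saturable truth
#' the emitted table reproduces the characteristic fall of CL/F at low
#' doses and its plateau once the enzyme is saturated.
#'
#' @param truth the generating `compound_record`.
#' @param doses ascending dose grid (mg).
#' @param residual_cv proportional noise CV on CL/F (fraction).
#' @param seed integer seed (used when `residual_cv > 0`).
#' @param opts solver options.
#' @return object of class `synthetic_study` whose `observations` is the
#'   CL/F table (`dose`, `phase`, `cl_over_f`).
#' @export
generate_dose_escalation <- function(truth,
                                     doses = c(25, 50, 100, 200, 400, 600,
                                               800),
                                     residual_cv = 0, seed = 1L,
                                     opts = solver_options(dt_out = 0.5)) {
  stopifnot(!is.unsorted(doses), residual_cv >= 0)
  tab <- dose_escalation_clf(truth, doses = doses, opts = opts)
  if (residual_cv > 0) {
    sdlog <- sqrt(log(1 + residual_cv^2))
    set.seed(seed)
    tab$cl_over_f <- tab$cl_over_f * exp(rnorm(nrow(tab), 0, sdlog))
  }
  structure(list(observations = tab, truth = truth,
                 design = list(doses = doses, days = 8),
                 residual_cv = residual_cv, seed = as.integer(seed)),
            class = "synthetic_study")
}

#' Synthetic DDI anchor
#'
#' Runs a paired DDI evaluation on the truth record and returns the exposure
#' ratio as a pseudo-observation, optionally jittered. Feeds
#' [calibration_targets()] in self-consistent recovery tests.
#'
#' @param truth victim (or perpetrator-of-probe) `compound_record`.
#' @param scenario one of `"itraconazole_100mg"` (itraconazole effect on
#'   100 mg single-dose truth) or `"midazolam_600mg"` (truth 600 mg QD
#'   effect on single-dose midazolam).
#' @param jitter_cv lognormal jitter CV (0 = deterministic).
#' @param seed integer seed (used when jittering).
#' @param opts solver options.
#' @return the anchor AUC ratio (fold).
#' @export
generate_ddi_anchor <- function(truth, scenario = c("itraconazole_100mg",
                                                    "midazolam_600mg"),
                                jitter_cv = 0, seed = 1L,
                                opts = solver_options(dt_out = 0.5)) {
  scenario <- match.arg(scenario)
  r <- if (scenario == "itraconazole_100mg") {
    ddi_ratio_mean_subject(
      truth, dose_regimen(truth$name, 100, "oral", start_time = 96),
      perpetrator_fixture("itraconazole"),
      dose_regimen("itraconazole", 200, "oral", 24, 9),
      t_end = 288, window_start = 96, metric = "auc_0_inf",
      opts = opts)$auc_ratio
  } else {
    mdz <- perpetrator_fixture("midazolam")
    ddi_ratio_mean_subject(
      mdz, dose_regimen("midazolam", 2, "oral", start_time = 168),
      truth, dose_regimen(truth$name, 600, "oral", 24, 8),
      t_end = 216, window_start = 168, metric = "auc_0_inf",
      opts = opts)$auc_ratio
  }
  if (jitter_cv > 0) {
    set.seed(seed)
    r <- r * exp(rnorm(1, 0, sqrt(log(1 + jitter_cv^2))))
  }
  r
}

#' Write a synthetic study as tidy CSV plus a truth manifest
#'
#' @param study a `synthetic_study`.
#' @param file CSV path; `<file>.truth.json` is written alongside.
#' @return `file`, invisibly.
#' @export
export_synthetic_csv <- function(study, file) {
  write.csv(study$observations, file, row.names = FALSE)
  truth <- study$truth
  manifest <- list(name = truth$name, seed = study$seed,
                   residual_cv = study$residual_cv,
                   km = if (!is.null(truth$cyp3a4)) truth$cyp3a4$km,
                   vmax = if (!is.null(truth$cyp3a4)) truth$cyp3a4$vmax,
                   cl_additional = truth$cl_additional,
                   kinact = if (!is.null(truth$interaction))
                     truth$interaction$kinact)
  jsonlite::write_json(manifest, paste0(file, ".truth.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(file)
}
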