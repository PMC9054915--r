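#' Define a virtual-trial DDI scenario
#'
#' A scenario pairs a victim regimen with an optional perpetrator regimen and
#' a trial design (number of trials x subjects per trial, seed, variability).
#' The "victim" is the compound whose exposure is summarized; for probe-
#' substrate scenarios the victim is the probe (e.g. midazolam) and the
#' perpetrator is the drug under study.
#'
#' @param name scenario label.
#' @param victim list with `record` (a `compound_record`) and `regimen`.
#' @param perpetrator `NULL`, or list with `record` and `regimen`.
#' @param n_trials,n_subjects trial design (both >= 1).
#' @param seed integer seed for the population draw.
#' @param cv_map between-subject CVs, see [variability_spec()].
#' @param t_end simulation horizon (h).
#' @param metric `"auc_tau"` (steady-state interval AUC, requires `tau`) or
#'   `"auc_0_inf"` (single-dose AUC with terminal extrapolation).
#' @param window_start start of the observation window (h), normally the
#'   time of the last (or only) victim dose.
#' @param tau interval width for `auc_tau` (h).
#' @param metadata annotative study metadata (age range, proportion female);
#'   does not alter the physiology.
#' @return object of class `scenario_config`.
#' @export
scenario_config <- function(name, victim, perpetrator = NULL, n_trials = 10,
                            n_subjects = 10, seed = 1L,
                            cv_map = default_cv_map(), t_end, metric = "auc_tau",
                            window_start, tau = 24, metadata = list()) {
  stopifnot(n_trials >= 1, n_subjects >= 1, t_end > 0)
  metric <- match.arg(metric, c("auc_tau", "auc_0_inf"))
  stopifnot(inherits(victim$record, "compound_record"),
            inherits(victim$regimen, "dose_regimen"))
  if (!is.null(perpetrator))
    stopifnot(inherits(perpetrator$record, "compound_record"),
              inherits(perpetrator$regimen, "dose_regimen"))
  structure(list(name = name, victim = victim, perpetrator = perpetrator,
                 trial = list(n_trials = as.integer(n_trials),
                              n_subjects = as.integer(n_subjects),
                              seed = as.integer(seed), cv_map = cv_map),
                 t_end = t_end, metric = metric,
                 window_start = window_start, tau = tau,
                 metadata = metadata),
            class = "scenario_config")
}

# exposure metrics of one simulated profile over the observation window
.window_metrics <- function(sim, compound, window_start, metric, tau, dose) {
  keep <- sim$time >= window_start - 1e-9
  tm <- sim$time[keep] - window_start
  cc <- sim$plasma[keep, compound]
  ns <- nca_single(tm, cc, dose = dose,
                   tau = if (metric == "auc_tau") tau else NULL)
  auc <- if (metric == "auc_tau") ns$auc_tau else ns$auc_0_inf
  win <- if (metric == "auc_tau") tm <= tau + 1e-9 else rep(TRUE, length(tm))
  list(auc = auc, cmax = max(cc[win]), tmax = tm[win][which.max(cc[win])],
       nca = ns)
}

#' Run a DDI scenario and summarize it
#'
#' Samples the virtual population, runs the paired trial, performs NCA per
#' subject and arm, and reports paired geometric-mean ratios with 90%
#' confidence intervals for AUC and Cmax.
#'
#' @param config a [scenario_config()].
#' @param opts solver options.
#' @return object of class `ddi_report`: `gmr_auc`, `gmr_cmax`
#'   ([paired_gmr()] results), `arms` (per-arm geometric mean and CV% of AUC
#'   and Cmax), `per_subject` (data.frame of the paired metrics) and the
#'   `config`.
#' @export
run_scenario <- function(config, opts = solver_options()) {
  trial <- simulate_trial(config, opts = opts)
  vic <- config$victim$record$name
  dose <- config$victim$regimen$dose
  rows <- lapply(trial$subjects, function(su) {
    a <- .window_metrics(su$alone, vic, config$window_start, config$metric,
                         config$tau, dose)
    b <- .window_metrics(su$combo, vic, config$window_start, config$metric,
                         config$tau, dose)
    data.frame(trial = su$trial, subject = su$id,
               auc_alone = a$auc, auc_combo = b$auc,
               cmax_alone = a$cmax, cmax_combo = b$cmax,
               tmax_alone = a$tmax, tmax_combo = b$tmax)
  })
  per <- do.call(rbind, rows)
  if (any(!is.finite(per$auc_alone)) || any(!is.finite(per$auc_combo)))
    stop("scenario '", config$name, "': non-estimable AUC for some subject")
  arms <- data.frame(
    arm = c("alone", "combo"),
    auc_geo_mean = c(geo_summary(per$auc_alone)$geo_mean,
                     geo_summary(per$auc_combo)$geo_mean),
    auc_geo_cv_pct = c(geo_summary(per$auc_alone)$geo_cv_pct,
                       geo_summary(per$auc_combo)$geo_cv_pct),
    cmax_geo_mean = c(geo_summary(per$cmax_alone)$geo_mean,
                      geo_summary(per$cmax_combo)$geo_mean),
    cmax_geo_cv_pct = c(geo_summary(per$cmax_alone)$geo_cv_pct,
                        geo_summary(per$cmax_combo)$geo_cv_pct))
  rep <- structure(list(
    gmr_auc = paired_gmr(per$auc_combo, per$auc_alone),
    gmr_cmax = paired_gmr(per$cmax_combo, per$cmax_alone),
    arms = arms, per_subject = per, config = config
  ), class = "ddi_report")
  # structural sanity: inhibitor-only scenarios cannot reduce exposure
  rep
}

#' @export
print.ddi_report <- function(x, ...) {
  cat("<ddi_report> ", x$config$name, "\n  AUC  ", sep = "")
  print(x$gmr_auc)
  cat("  Cmax ")
  print(x$gmr_cmax)
  invisible(x)
}

#' Deterministic DDI ratio on the mean subject
#'
#' Runs the paired simulation once on the unperturbed physiology (no
#' between-subject variability) and returns exposure ratios. This is the
#' fast, noise-free evaluation used by the calibration objective and fixture
#' qualification.
#'
#' @param victim,perp `compound_record`s (`perp` may be `NULL`).
#' @param victim_reg,perp_reg `dose_regimen`s.
#' @param t_end horizon (h).
#' @param window_start observation window start (h).
#' @param metric,tau see [scenario_config()].
#' @param opts solver options.
#' @return list with `auc_ratio`, `cmax_ratio`, `auc_alone`, `auc_combo`,
#'   `cmax_alone`, `cmax_combo`.
#' @export
ddi_ratio_mean_subject <- function(victim, victim_reg, perp, perp_reg, t_end,
                                   window_start, metric = "auc_0_inf",
                                   tau = 24, opts = solver_options()) {
  phys <- default_healthy_volunteer()
  kv <- scaled_kp_set(victim, phys)
  alone <- simulate_subject(list(victim), list(victim_reg), phys, t_end,
                            kpps = list(kv), opts = opts)
  a <- .window_metrics(alone, victim$name, window_start, metric, tau,
                       victim_reg$dose)
  if (is.null(perp) || perp_reg$dose == 0) {
    return(list(auc_ratio = 1, cmax_ratio = 1, auc_alone = a$auc,
                auc_combo = a$auc, cmax_alone = a$cmax, cmax_combo = a$cmax))
  }
  kp <- scaled_kp_set(perp, phys)
  combo <- simulate_subject(list(victim, perp), list(victim_reg, perp_reg),
                            phys, t_end, kpps = list(kv, kp), opts = opts)
  b <- .window_metrics(combo, victim$name, window_start, metric, tau,
                       victim_reg$dose)
  list(auc_ratio = b$auc / a$auc, cmax_ratio = b$cmax / a$cmax,
       auc_alone = a$auc, auc_combo = b$auc,
       cmax_alone = a$cmax, cmax_combo = b$cmax)
}

# ---- canned scenario builders ------------------------------------------

#' Calibration-study scenario: itraconazole on single-dose ipatasertib
#'
#' Itraconazole 200 mg QD on days 1-9; ipatasertib 100 mg single oral dose on
#' day 5; 12-day horizon; single-dose AUC extrapolated to infinity.
#'
#' @param victim ipatasertib record (possibly a calibration candidate).
#' @param n_trials,n_subjects,seed trial design.
#' @return `scenario_config`.
#' @export
scenario_itz_calibration <- function(victim = ipatasertib_final(),
                                     n_trials = 10, n_subjects = 15,
                                     seed = 101L) {
  scenario_config(
    name = "itraconazole-ddi-100mg",
    victim = list(record = victim,
                  regimen = dose_regimen(victim$name, 100, "oral",
                                         start_time = 96)),
    perpetrator = list(record = perpetrator_fixture("itraconazole"),
                       regimen = dose_regimen("itraconazole", 200, "oral",
                                              interval = 24, n_doses = 9)),
    n_trials = n_trials, n_subjects = n_subjects, seed = seed,
    t_end = 288, metric = "auc_0_inf", window_start = 96,
    metadata = list(age_range = c(22, 52), prop_female = 0.67))
}

#' Perpetrator-study scenario: ipatasertib on single-dose midazolam
#'
#' Ipatasertib QD on days 1-8; midazolam 2 mg single oral dose on day 8;
#' midazolam AUC extrapolated to infinity.
#'
#' @param ipa ipatasertib record.
#' @param ipa_dose ipatasertib daily dose (mg), 600 for the calibration
#'   study, 400 for the application scenario.
#' @param n_trials,n_subjects,seed trial design.
#' @return `scenario_config`.
#' @export
scenario_mdz_victim <- function(ipa = ipatasertib_final(), ipa_dose = 600,
                                n_trials = 10, n_subjects = 13, seed = 102L) {
  scenario_config(
    name = sprintf("midazolam-with-ipatasertib-%gmg", ipa_dose),
    victim = list(record = perpetrator_fixture("midazolam"),
                  regimen = dose_regimen("midazolam", 2, "oral",
                                         start_time = 168)),
    perpetrator = list(record = ipa,
                       regimen = dose_regimen(ipa$name, ipa_dose, "oral",
                                              interval = 24, n_doses = 8)),
    n_trials = n_trials, n_subjects = n_subjects, seed = seed,
    t_end = 192 + 24, metric = "auc_0_inf", window_start = 168,
    metadata = list(age_range = c(37, 76), prop_female = 0.69))
}

#' Application scenario: 21-day perpetrator co-administration
#'
#' Ipatasertib QD for 21 days with one of the registered CYP3A4 perpetrators
#' dosed concurrently (itraconazole 200 mg QD, erythromycin 500 mg TID,
#' diltiazem 120 mg BID, fluvoxamine 100 mg QD, rifampin 600 mg QD,
#' efavirenz 600 mg QD); steady-state AUC0-24h and Cmax on day 21.
#'
#' @param perp_name registered perpetrator name.
#' @param ipa ipatasertib record.
#' @param ipa_dose ipatasertib dose (mg), 400 by default.
#' @param n_trials,n_subjects,seed trial design.
#' @return `scenario_config`.
#' @export
scenario_application <- function(perp_name, ipa = ipatasertib_final(),
                                 ipa_dose = 400, n_trials = 10,
                                 n_subjects = 10, seed = 103L) {
  regs <- list(
    itraconazole = c(dose = 200, interval = 24, n = 21),
    erythromycin = c(dose = 500, interval = 8, n = 63),
    diltiazem    = c(dose = 120, interval = 12, n = 42),
    fluvoxamine  = c(dose = 100, interval = 24, n = 21),
    rifampin     = c(dose = 600, interval = 24, n = 21),
    efavirenz    = c(dose = 600, interval = 24, n = 21))
  if (!perp_name %in% names(regs))
    stop("no registered application regimen for ", perp_name)
  rg <- regs[[perp_name]]
  scenario_config(
    name = sprintf("ipatasertib-%gmg-with-%s", ipa_dose, perp_name),
    victim = list(record = ipa,
                  regimen = dose_regimen(ipa$name, ipa_dose, "oral",
                                         interval = 24, n_doses = 21)),
    perpetrator = list(record = perpetrator_fixture(perp_name),
                       regimen = dose_regimen(perp_name, rg[["dose"]], "oral",
                                              interval = rg[["interval"]],
                                              n_doses = rg[["n"]])),
    n_trials = n_trials, n_subjects = n_subjects, seed = seed,
    t_end = 504, metric = "auc_tau", window_start = 480, tau = 24,
    metadata = list(age_range = c(20, 95), prop_female = 0.5))
}

#' Dose-reduction comparison: 200 mg + moderate inhibitor vs 400 mg alone
#'
#' Simulates ipatasertib 200 mg QD co-dosed with a moderate CYP3A4 inhibitor
#' and ipatasertib 400 mg QD alone, sharing the same trial seed (hence the
#' same virtual subjects), and reports the paired ratio of steady-state
#' day-21 AUCs with a 90% confidence interval.
#'
#' @param inhibitor `"erythromycin"` or `"diltiazem"` (or any registered
#'   perpetrator; `"none"` compares 400 mg with itself via a zero-dose
#'   perpetrator arm).
#' @param reduced_dose reduced victim dose (mg), default 200.
#' @param n_trials,n_subjects,seed trial design.
#' @param opts solver options.
#' @return list with `ratio` ([paired_gmr()] of reduced+inhibitor over
#'   400 mg alone), and the two underlying reports.
#' @export
dose_reduction_analysis <- function(inhibitor = "erythromycin",
                                    reduced_dose = 200, n_trials = 10,
                                    n_subjects = 10, seed = 104L,
                                    opts = solver_options()) {
  cfg_red <- scenario_application(inhibitor, ipa_dose = reduced_dose,
                                  n_trials = n_trials,
                                  n_subjects = n_subjects, seed = seed)
  cfg_ref <- cfg_red
  cfg_ref$victim$regimen <- dose_regimen(cfg_red$victim$record$name, 400,
                                         "oral", interval = 24, n_doses = 21)
  rep_red <- run_scenario(cfg_red, opts = opts)
  rep_ref <- run_scenario(cfg_ref, opts = opts)
  ratio <- paired_gmr(rep_red$per_subject$auc_combo,
                      rep_ref$per_subject$auc_alone)
  list(ratio = ratio, reduced = rep_red, reference = rep_ref)
}

# ---- fixture qualification ---------------------------------------------

#' Qualify a perpetrator fixture against its interaction-class envelope
#'
#' Each fixture must reproduce the behaviour of its CYP3A4 interaction
#' class on a deterministic mean-subject benchmark: strong inhibitors raise
#' a sensitive substrate's AUC at least 5-fold, moderate inhibitors 2-5-fold,
#' weak inhibitors 1.25-2-fold, strong inducers cut it to at most 0.2-fold
#' and moderate inducers to 0.2-0.8-fold. Fluvoxamine must additionally
#' leave 400 mg ipatasertib essentially unchanged (< 1.25-fold), and the
#' midazolam probe must be predominantly CYP3A4-cleared (fm > 0.9).
#'
#' @param name registered fixture name.
#' @param record optional replacement record (e.g. a deliberately corrupted
#'   copy in a negative-control test); defaults to the shipped fixture.
#' @param opts solver options.
#' @return object of class `qualification_report`: `pass` and a `checks`
#'   data.frame (`check`, `value`, `rule`, `pass`).
#' @export
qualify_fixture <- function(name, record = NULL, opts = solver_options()) {
  rec <- if (is.null(record)) perpetrator_fixture(name) else record
  checks <- list()
  add <- function(check, value, rule, pass)
    checks[[length(checks) + 1L]] <<- data.frame(check = check, value = value,
                                                 rule = rule, pass = pass)
  mdz_ratio <- function() {
    reg <- switch(name,
      itraconazole = dose_regimen(rec$name, 200, "oral", 24, 8),
      erythromycin = dose_regimen(rec$name, 500, "oral", 8, 24),
      diltiazem    = dose_regimen(rec$name, 120, "oral", 12, 16),
      fluvoxamine  = dose_regimen(rec$name, 100, "oral", 24, 8),
      rifampin     = dose_regimen(rec$name, 600, "oral", 24, 8),
      efavirenz    = dose_regimen(rec$name, 600, "oral", 24, 8))
    mdz <- perpetrator_fixture("midazolam")
    ddi_ratio_mean_subject(mdz, dose_regimen("midazolam", 2, "oral",
                                             start_time = 168),
                           rec, reg, t_end = 216, window_start = 168,
                           opts = opts)$auc_ratio
  }
  if (name == "midazolam") {
    fm <- fm_cyp3a4(rec)$fm_total
    add("fm_cyp3a4_trace", fm, "> 0.9", fm > 0.9)
  } else if (name %in% c("itraconazole", "erythromycin", "diltiazem",
                         "fluvoxamine", "rifampin", "efavirenz")) {
    r <- mdz_ratio()
    rule <- switch(name,
      itraconazole = c(5, Inf), erythromycin = c(2, 5), diltiazem = c(2, 5),
      fluvoxamine = c(1.25, 2), rifampin = c(0, 0.2), efavirenz = c(0.2, 0.8))
    add("midazolam_auc_ratio", r,
        sprintf("in [%g, %g]", rule[1], rule[2]),
        r >= rule[1] & r <= rule[2])
    if (name == "fluvoxamine") {
      ipa <- ipatasertib_final()
      rr <- ddi_ratio_mean_subject(
        ipa, dose_regimen(ipa$name, 400, "oral", 24, 8),
        rec, dose_regimen(rec$name, 100, "oral", 24, 8),
        t_end = 216, window_start = 168, metric = "auc_tau", tau = 24,
        opts = opts)$auc_ratio
      add("ipatasertib_auc_ratio", rr, "< 1.25", rr < 1.25)
    }
  } else stop("no qualification rules registered for ", name)
  checks <- do.call(rbind, checks)
  structure(list(name = name, pass = all(checks$pass), checks = checks),
            class = "qualification_report")
}

#' @export
print.qualification_report <- function(x, ...) {
  cat("<qualification_report> ", x$name, ": ",
      if (x$pass) "PASS" else "FAIL", "\n", sep = "")
  print(x$checks, row.names = FALSE)
  invisible(x)
}
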