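#' Calibration anchor targets
#'
#' The clinical anchors the stepwise optimization reproduces: the
#' itraconazole DDI on 100 mg single-dose ipatasertib (observed AUC ratio
#' 5.45, observed ipatasertib-alone AUC0-inf 327 ng*h/mL), the midazolam DDI
#' under 600 mg QD ipatasertib (observed AUC ratio 2.22), and optionally a
#' dose-escalation oral-clearance table for final-model selection.
#'
#' @param itz_auc_ratio itraconazole-study AUC ratio (fold).
#' @param ipa_auc_ref ipatasertib-alone AUC0-inf in the same study
#'   (ng*h/mL).
#' @param mdz_auc_ratio midazolam-study AUC ratio (fold).
#' @param dose_escalation `NULL` or a data.frame (`dose`, `phase`,
#'   `cl_over_f`) as produced by [generate_dose_escalation()].
#' @return object of class `calibration_targets`.
#' @export
calibration_targets <- function(itz_auc_ratio = 5.45, ipa_auc_ref = 327,
                                mdz_auc_ratio = 2.22,
                                dose_escalation = NULL) {
  stopifnot(itz_auc_ratio > 0, ipa_auc_ref > 0, mdz_auc_ratio > 0)
  structure(list(itz_auc_ratio = itz_auc_ratio, ipa_auc_ref = ipa_auc_ref,
                 mdz_auc_ratio = mdz_auc_ratio,
                 dose_escalation = dose_escalation),
            class = "calibration_targets")
}

#' Retrograde intrinsic clearance of CYP3A4
#'
#' Back-computes the per-pmol hepatic CYP3A4 intrinsic clearance from an
#' observed systemic plasma clearance: the hepatic plasma clearance
#' (IV minus renal) is converted to blood units, the well-stirred model
#' `CL_H = Q_H fu_B CLu_int / (Q_H + fu_B CLu_int)` is inverted, the
#' assigned additional intrinsic clearance is subtracted, and the remainder
#' is scaled by the hepatic enzyme content.
#'
#' @param cl_iv_plasma total IV plasma clearance (L/h).
#' @param cl_renal renal plasma clearance (L/h).
#' @param cl_additional additional intrinsic hepatic clearance (L/h).
#' @param fu fraction unbound in plasma.
#' @param bp blood:plasma ratio.
#' @param phys a `system_physiology`.
#' @return CYP3A4 intrinsic clearance in uL/min/pmol.
#' @export
retrograde_clint <- function(cl_iv_plasma, cl_renal, cl_additional, fu, bp,
                             phys = default_healthy_volunteer()) {
  if (cl_iv_plasma <= cl_renal)
    stop("IV clearance must exceed renal clearance")
  clh_b <- (cl_iv_plasma - cl_renal) / bp
  qh <- sum(phys$tissue_blood_flows[c("liver", "gut", "spleen")])
  if (clh_b >= qh)
    stop("hepatic clearance (", signif(clh_b, 4),
         " L/h blood) at or above hepatic blood flow (", signif(qh, 4),
         " L/h): unphysical")
  fub <- fu / bp
  clint_total <- clh_b * qh / (fub * (qh - clh_b))  # L/h
  clint_cyp <- clint_total - cl_additional
  if (clint_cyp < 0)
    stop("cl_additional exceeds the total hepatic intrinsic clearance")
  clint_cyp * 1e6 / 60 / hepatic_cyp3a4_total(phys)  # uL/min/pmol
}

#' Forward well-stirred hepatic plasma clearance (retrograde inverse)
#'
#' Composes the plasma clearance implied by a per-pmol CYP3A4 intrinsic
#' clearance plus additional intrinsic and renal clearance; the exact
#' inverse of [retrograde_clint()], used for round-trip verification.
#'
#' @param clint_cyp CYP3A4 intrinsic clearance (uL/min/pmol).
#' @inheritParams retrograde_clint
#' @return total IV plasma clearance (L/h).
#' @export
forward_cl_iv <- function(clint_cyp, cl_renal, cl_additional, fu, bp,
                          phys = default_healthy_volunteer()) {
  clint_total <- clint_cyp * hepatic_cyp3a4_total(phys) * 60 / 1e6 +
    cl_additional
  qh <- sum(phys$tissue_blood_flows[c("liver", "gut", "spleen")])
  fub <- fu / bp
  clh_b <- qh * fub * clint_total / (qh + fub * clint_total)
  clh_b * bp + cl_renal
}

#' Maximal metabolic rate from intrinsic clearance and Km
#'
#' `Vmax = CLint x Km` with unit bookkeeping: uL/min/pmol x umol/L =
#' pmol/min/pmol.
#'
#' @param clint intrinsic clearance (uL/min/pmol).
#' @param km Michaelis constant (uM).
#' @return Vmax (pmol/min/pmol).
#' @export
#' @examples
#' retrograde_vmax(0.692, 0.195)
retrograde_vmax <- function(clint, km) {
  stopifnot(clint > 0, km > 0)
  clint * km
}

#' A calibration candidate model
#'
#' One (Km, Vmax, CL_additional, kinact) set, tagged with the steps that
#' produced it.
#'
#' @param km Km,CYP3A4 (uM).
#' @param vmax Vmax,CYP3A4 (pmol/min/pmol).
#' @param cl_additional additional intrinsic hepatic clearance (L/h).
#' @param kinact inactivation rate (1/h); `NA` before step 2.
#' @param provenance character vector of fitted-step labels.
#' @return object of class `candidate_model`.
#' @export
candidate_model <- function(km, vmax, cl_additional, kinact = NA,
                            provenance = character()) {
  stopifnot(km > 0, vmax > 0, cl_additional >= 0)
  structure(list(km = km, vmax = vmax, cl_additional = cl_additional,
                 kinact = kinact, provenance = provenance),
            class = "candidate_model")
}

#' Apply a candidate to the ipatasertib record
#'
#' @param cand a `candidate_model`.
#' @param base the base record whose non-calibrated parameters are kept.
#' @param tdi include the candidate's TDI parameters (`FALSE` reproduces the
#'   step-1 configuration, which excludes auto-inactivation).
#' @return a `compound_record`.
#' @export
apply_candidate <- function(cand, base = ipatasertib_final(), tdi = TRUE) {
  rec <- base
  rec$cyp3a4$vmax <- cand$vmax
  rec$cyp3a4$km <- cand$km
  rec$cl_additional <- cand$cl_additional
  if (!tdi || is.na(cand$kinact)) {
    rec <- without_tdi(rec)
  } else {
    rec$interaction$kinact <- cand$kinact
    if (is.null(rec$interaction$kapp)) rec$interaction$kapp <- 9.66
  }
  validate_compound(rec)
}

# deterministic step-1 objective pieces: mean-subject 100 mg single-dose
# exposure and its itraconazole ratio (TDI excluded, as in the study step)
.step1_eval <- function(vmax, cl_add, km, base, opts) {
  cand <- candidate_model(km = km, vmax = vmax, cl_additional = cl_add)
  rec <- apply_candidate(cand, base, tdi = FALSE)
  itz <- perpetrator_fixture("itraconazole")
  r <- ddi_ratio_mean_subject(
    rec, dose_regimen(rec$name, 100, "oral", start_time = 96),
    itz, dose_regimen("itraconazole", 200, "oral", 24, 9),
    t_end = 288, window_start = 96, metric = "auc_0_inf", opts = opts)
  list(ratio = r$auc_ratio, auc = r$auc_alone)
}

#' Calibration step 1: anchor Vmax and CL_additional to the itraconazole DDI
#'
#' With Km fixed, jointly adjusts Vmax,CYP3A4 and CL_additional (bounded
#' derivative-free minimization on the log scale, multistart) so that the
#' simulated 100 mg single-dose itraconazole AUC ratio matches the observed
#' ratio and the simulated ipatasertib-alone AUC0-inf matches the observed
#' exposure. TDI parameters are excluded from this step. The objective is
#' the sum of squared log deviations; convergence requires < 1e-6.
#'
#' @param km_fixed the fixed Km (uM); the study grid was
#'   `c(0.195, 1.95, 19.47)`.
#' @param targets a [calibration_targets()].
#' @param base base ipatasertib record.
#' @param opts solver options (calibration uses a coarser output grid for
#'   speed; tolerances unchanged).
#' @return a `candidate_model` with provenance `"step1-itraconazole"`.
#' @export
fit_step1_itraconazole <- function(km_fixed, targets = calibration_targets(),
                                   base = ipatasertib_final(),
                                   opts = solver_options(dt_out = 0.5)) {
  stopifnot(km_fixed > 0)
  # initial guess: keep the final-model CLint (Vmax/Km) scale at this Km
  v0 <- retrograde_vmax(0.692, km_fixed)
  c0 <- max(base$cl_additional, 0.5)
  resid <- function(lp) {
    ev <- .step1_eval(exp(lp[1]), exp(lp[2]), km_fixed, base, opts)
    c(log(ev$ratio / targets$itz_auc_ratio),
      log(ev$auc / targets$ipa_auc_ref))
  }
  # two smooth targets, two log-parameters: damped Newton with a numerical
  # Jacobian; multistart Nelder-Mead on the squared residual as fallback
  solve_newton <- function(p0) {
    p <- p0
    r <- resid(p)
    for (it in 1:12) {
      if (sum(r^2) < 1e-8) return(list(par = p, value = sum(r^2)))
      h <- 0.05
      J <- matrix(0, 2, 2)
      for (j in 1:2) {
        ph <- p; ph[j] <- ph[j] + h
        J[, j] <- (resid(ph) - r) / h
      }
      step <- tryCatch(solve(J, -r), error = function(e) NULL)
      if (is.null(step)) break
      step <- pmin(pmax(step, -1.5), 1.5)
      lam <- 1
      repeat {
        rn <- resid(p + lam * step)
        if (sum(rn^2) < sum(r^2) || lam < 0.1) break
        lam <- lam / 2
      }
      p <- p + lam * step
      r <- rn
    }
    list(par = p, value = sum(r^2))
  }
  best <- solve_newton(log(c(v0, c0)))
  if (best$value >= 1e-6) {
    obj <- function(lp) sum(resid(lp)^2)
    for (m in c(0.3, 3)) {
      fit <- optim(log(c(v0 * m, c0 * m)), obj, method = "Nelder-Mead",
                   control = list(abstol = 1e-8, reltol = 1e-10, maxit = 150))
      if (fit$value < best$value) best <- fit
      if (best$value < 1e-6) break
    }
  }
  if (best$value >= 1e-6)
    stop("step-1 calibration did not converge (objective ",
         format(best$value), ") at Km ", km_fixed)
  candidate_model(km = km_fixed, vmax = exp(best$par[1]),
                  cl_additional = exp(best$par[2]),
                  provenance = "step1-itraconazole")
}

#' Calibration step 2: anchor kinact to the midazolam DDI
#'
#' One-dimensional bounded search on the inactivation rate so the simulated
#' midazolam AUC ratio under 600 mg QD ipatasertib matches the observed
#' ratio; Ki and Kapp stay at their in vitro values. The ratio is monotone
#' in kinact, so a bracket plus Brent root refinement suffices.
#'
#' @param model a step-1 `candidate_model`.
#' @param targets a [calibration_targets()].
#' @param base base ipatasertib record.
#' @param kinact_max upper bracket (1/h); 2.6 is the in vitro value.
#' @param opts solver options.
#' @return the candidate with fitted `kinact`, provenance extended.
#' @export
fit_step2_kinact <- function(model, targets = calibration_targets(),
                             base = ipatasertib_final(), kinact_max = 2.6,
                             opts = solver_options(dt_out = 0.5)) {
  mdz <- perpetrator_fixture("midazolam")
  phys <- default_healthy_volunteer()
  kv <- scaled_kp_set(mdz, phys)
  mdz_reg <- dose_regimen("midazolam", 2, "oral", start_time = 168)
  alone <- simulate_subject(list(mdz), list(mdz_reg), phys, t_end = 216,
                            kpps = list(kv), opts = opts)
  auc_alone <- .window_metrics(alone, "midazolam", 168, "auc_0_inf", 24,
                               2)$auc
  ratio_at <- function(kinact) {
    cand <- model; cand$kinact <- kinact
    rec <- apply_candidate(cand, base, tdi = kinact > 0)
    combo <- simulate_subject(
      list(mdz, rec), list(mdz_reg, dose_regimen(rec$name, 600, "oral", 24, 8)),
      phys, t_end = 216, kpps = list(kv, scaled_kp_set(rec, phys)),
      opts = opts)
    .window_metrics(combo, "midazolam", 168, "auc_0_inf", 24, 2)$auc /
      auc_alone
  }
  f <- function(k) log(ratio_at(k) / targets$mdz_auc_ratio)
  f0 <- f(0)
  if (f0 >= 0) {
    if (f0 < log(1.05)) {
      model$kinact <- 0
      model$provenance <- c(model$provenance, "step2-midazolam(floor)")
      return(model)
    }
    stop("midazolam target below the kinact = 0 floor (ratio ",
         signif(exp(f0) * targets$mdz_auc_ratio, 4), ")")
  }
  fmax <- f(kinact_max)
  if (fmax < 0)
    stop("midazolam target above the achievable range at kinact <= ",
         kinact_max, " (ratio ",
         signif(exp(fmax) * targets$mdz_auc_ratio, 4), ")")
  r <- uniroot(f, c(1e-4, kinact_max), tol = 1e-6,
               f.lower = f0, f.upper = fmax)
  model$kinact <- r$root
  model$provenance <- c(model$provenance, "step2-midazolam")
  model
}

#' Sensitivity scan of an inhibitory parameter
#'
#' Re-simulates the midazolam DDI with one inhibitory parameter (`ki` or
#' `kinact`) scaled over a multiplier grid, everything else fixed, and
#' reports the AUC ratio per grid point with a monotone-direction
#' diagnostic.
#'
#' @param model a `candidate_model` (with kinact fitted or assigned).
#' @param parameter `"ki"` or `"kinact"`.
#' @param grid positive multipliers applied to the parameter.
#' @param ipa_dose perpetrator dose (mg QD x 8 days).
#' @param base base ipatasertib record.
#' @param opts solver options.
#' @return data.frame with `multiplier`, `value`, `auc_ratio`; attribute
#'   `"monotone"` gives the sign of the trend.
#' @export
sensitivity_scan <- function(model, parameter = c("kinact", "ki"),
                             grid = c(0.3, 1, 3), ipa_dose = 600,
                             base = ipatasertib_final(),
                             opts = solver_options(dt_out = 0.5)) {
  parameter <- match.arg(parameter)
  stopifnot(all(grid > 0))
  mdz <- perpetrator_fixture("midazolam")
  ratios <- vapply(grid, function(m) {
    rec <- apply_candidate(model, base, tdi = TRUE)
    if (parameter == "ki") rec$interaction$ki <- rec$interaction$ki * m
    else rec$interaction$kinact <- rec$interaction$kinact * m
    ddi_ratio_mean_subject(
      mdz, dose_regimen("midazolam", 2, "oral", start_time = 168),
      rec, dose_regimen(rec$name, ipa_dose, "oral", 24, 8),
      t_end = 216, window_start = 168, metric = "auc_0_inf",
      opts = opts)$auc_ratio
  }, 0)
  vals <- switch(parameter, ki = base$interaction$ki * grid,
                 kinact = model$kinact * grid)
  out <- data.frame(multiplier = grid, value = vals, auc_ratio = ratios)
  attr(out, "monotone") <- if (all(diff(ratios[order(grid)]) >= 0)) 1
    else if (all(diff(ratios[order(grid)]) <= 0)) -1 else 0
  out
}

#' Simulated oral-clearance versus dose table
#'
#' Single-dose and day-8 steady-state apparent oral clearance (`CL/F`)
#' across a dose grid, on the mean subject. The diagnostic for saturable
#' first-pass and systemic metabolism: CL/F falls with dose until the
#' enzyme saturates.
#'
#' @param rec a `compound_record`.
#' @param doses dose grid (mg), ascending.
#' @param opts solver options.
#' @return data.frame with `dose`, `phase` (`"single"`/`"steady_state"`),
#'   `cl_over_f` (L/h).
#' @export
dose_escalation_clf <- function(rec, doses = c(25, 50, 100, 200, 400, 600,
                                               800),
                                opts = solver_options(dt_out = 0.5)) {
  stopifnot(!is.unsorted(doses))
  phys <- default_healthy_volunteer()
  kpp <- scaled_kp_set(rec, phys)
  rows <- lapply(doses, function(d) {
    # 8 days QD: day-1 dose gives the single-dose profile (pre-accumulation
    # sampling), day-8 interval gives steady state
    sim <- simulate_subject(list(rec),
                            list(dose_regimen(rec$name, d, "oral", 24, 8)),
                            phys, t_end = 264, kpps = list(kpp), opts = opts)
    ss <- .window_metrics(sim, rec$name, 168, "auc_tau", 24, d)
    sd1 <- simulate_subject(list(rec),
                            list(dose_regimen(rec$name, d, "oral")),
                            phys, t_end = 192, kpps = list(kpp), opts = opts)
    si <- .window_metrics(sd1, rec$name, 0, "auc_0_inf", 24, d)
    data.frame(dose = d, phase = c("single", "steady_state"),
               cl_over_f = c(si$nca$cl_over_f, d * 1e6 / ss$auc / 1000))
  })
  do.call(rbind, rows)
}

#' Calibration step 3: select the final model by the dose-escalation trend
#'
#' Simulates CL/F versus dose for each candidate and returns the candidate
#' minimizing the squared log-deviation from the observed (synthetic)
#' dose-escalation table. Ties within 1e-9 go to the lowest Km.
#'
#' @param candidates list of `candidate_model`s (each through steps 1-2).
#' @param dose_escalation_data data.frame (`dose`, `phase`, `cl_over_f`).
#' @param base base ipatasertib record.
#' @param opts solver options.
#' @return the selected `candidate_model`; the per-candidate objectives are
#'   attached as attribute `"objectives"`.
#' @export
select_final_model <- function(candidates, dose_escalation_data,
                               base = ipatasertib_final(),
                               opts = solver_options(dt_out = 0.5)) {
  stopifnot(length(candidates) >= 2)
  obs <- dose_escalation_data
  objs <- vapply(candidates, function(cand) {
    rec <- apply_candidate(cand, base, tdi = TRUE)
    sim <- dose_escalation_clf(rec, doses = sort(unique(obs$dose)),
                               opts = opts)
    merged <- merge(obs, sim, by = c("dose", "phase"),
                    suffixes = c("_obs", "_sim"))
    sum(log(merged$cl_over_f_sim / merged$cl_over_f_obs)^2)
  }, 0)
  best <- min(objs)
  tied <- which(objs <= best + 1e-9)
  kms <- vapply(candidates[tied], function(x) x$km, 0)
  sel <- candidates[[tied[which.min(kms)]]]
  sel$provenance <- c(sel$provenance, "step3-dose-escalation")
  attr(sel, "objectives") <- data.frame(
    km = vapply(candidates, function(x) x$km, 0), objective = objs)
  sel
}
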