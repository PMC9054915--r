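#' Solver options for the PBPK engine
#'
#' Stiff implicit integration (lsoda switches to BDF where needed) with tight
#' tolerances; doses are handled as integration restarts at event times, no
#' impulse smoothing.
#'
#' @param rtol relative tolerance.
#' @param atol absolute tolerance (mg or mg/L per state).
#' @param dt_out output grid spacing (h).
#' @param maxsteps maximal internal steps per output interval.
#' @return list of solver options.
#' @export
solver_options <- function(rtol = 1e-8, atol = 1e-10, dt_out = 0.25,
                           maxsteps = 5e5) {
  list(rtol = rtol, atol = atol, dt_out = dt_out, maxsteps = maxsteps)
}

# parameter/state bookkeeping mirrored in src/pbpk.c
.NGLOB <- 28L
.NPCPD <- 27L
.NSCPD <- 18L

.state_names <- function(compounds) {
  nms <- c("E_liver", "E_gut")
  for (rec in compounds) {
    nms <- c(nms, paste0(rec$name, ".",
                         c("depot", .TISSUES, "arterial", "venous",
                           "cum_gut_met", "cum_cyp_met", "cum_add_met",
                           "cum_renal")))
  }
  nms
}

.pbpk_parms <- function(compounds, kpps, phys) {
  p <- numeric(.NGLOB + 2L * .NPCPD)
  p[1] <- length(compounds)
  p[2] <- phys$cardiac_output
  q <- numeric(11)
  names(q) <- .TISSUES
  q["lung"] <- phys$cardiac_output
  q[.SYSTEMIC] <- phys$tissue_blood_flows[.SYSTEMIC]
  p[3:13] <- q
  p[14:24] <- phys$tissue_volumes[.TISSUES]
  p[25] <- phys$tissue_volumes[["arterial_blood"]]
  p[26] <- phys$tissue_volumes[["venous_blood"]]
  p[27] <- phys$kdeg_hepatic
  p[28] <- phys$kdeg_gut
  for (i in seq_along(compounds)) {
    rec <- compounds[[i]]
    b <- .NGLOB + (i - 1L) * .NPCPD
    vmax_li <- vmax_gu <- 0
    km <- 1
    if (!is.null(rec$cyp3a4) && rec$cyp3a4$vmax > 0) {
      vmax_li <- rec$cyp3a4$vmax * hepatic_cyp3a4_total(phys) * 60 / 1e6
      vmax_gu <- rec$cyp3a4$vmax * phys$cyp3a4_gut_total * 1000 * 60 / 1e6
      km <- rec$cyp3a4$km * rec$cyp3a4$fu_mic
    }
    it <- rec$interaction
    fumic <- if (!is.null(it) && !is.null(it$fu_mic)) it$fu_mic else 1
    inv_ki <- if (!is.null(it) && !is.null(it$ki)) 1 / (it$ki * fumic) else 0
    kapp <- if (!is.null(it) && !is.null(it$kapp)) it$kapp * fumic else 1
    kinact <- if (!is.null(it) && !is.null(it$kinact)) it$kinact else 0
    indmax <- if (!is.null(it) && !is.null(it$ind_max)) it$ind_max else 0
    indc50 <- if (!is.null(it) && !is.null(it$ind_c50)) it$ind_c50 * fumic else 1
    p[b + 1:16] <- c(rec$mw, rec$bp_ratio, rec$fu_plasma, rec$ka, rec$q_gut,
                     rec$fu_gut, rec$cl_renal, rec$cl_additional,
                     vmax_li, vmax_gu, km, inv_ki, kapp, kinact, indmax,
                     indc50)
    p[b + 17:27] <- kpps[[i]][.TISSUES]
  }
  p
}

#' Simulate one subject
#'
#' Integrates the coupled whole-body PBPK system for one victim compound,
#' optionally co-dosed with a perpetrator. Perfusion-limited tissue
#' distribution; first-order oral absorption into a depot with the fraction
#' absorbed applied at depot filling; dynamic gut-wall escape
#' `Fg(t) = Qgut / (Qgut + fu_gut * CLu_int_gut(t))` with saturable,
#' inhibitable, inducible gut CYP3A4; saturable hepatic CYP3A4 on the unbound
#' liver water concentration plus additional intrinsic hepatic clearance;
#' renal clearance of venous plasma; and shared liver/gut enzyme pools with
#' first-order turnover, mechanism-based inactivation and induction.
#'
#' @param compounds a `compound_record` or list of 1-2 records (victim
#'   first).
#' @param regimens a `dose_regimen` or list of regimens; each must reference
#'   a supplied compound by name.
#' @param phys a `system_physiology`.
#' @param t_end simulation horizon (h); must cover all doses.
#' @param kpps optional list of scaled Kp sets (per compound); computed with
#'   [scaled_kp_set()] when omitted.
#' @param opts solver options, see [solver_options()].
#' @return an object of class `pbpk_sim` with elements `time` (h), `plasma`
#'   (matrix of venous plasma concentrations, ng/mL, one column per
#'   compound), `enzyme` (liver/gut pool fractions), `state` (full state
#'   matrix), `compounds`, `regimens`, `dosing` (event table) and `opts`.
#' @export
#' @examples
#' \donttest{
#' sim <- simulate_subject(ipatasertib_final(),
#'                         dose_regimen("ipatasertib", 100), t_end = 96)
#' max(sim$plasma[, "ipatasertib"])
#' }
simulate_subject <- function(compounds, regimens, phys = default_healthy_volunteer(),
                             t_end, kpps = NULL, opts = solver_options()) {
  if (inherits(compounds, "compound_record")) compounds <- list(compounds)
  if (inherits(regimens, "dose_regimen")) regimens <- list(regimens)
  stopifnot(length(compounds) %in% 1:2, length(regimens) >= 1, t_end > 0)
  cnames <- vapply(compounds, function(r) r$name, "")
  if (anyDuplicated(cnames)) stop("duplicate compound names")
  if (is.null(kpps)) kpps <- lapply(compounds, scaled_kp_set, phys = phys)

  # dose events
  ev <- list()
  for (reg in regimens) {
    ci <- match(reg$compound, cnames)
    if (is.na(ci)) stop("regimen references unknown compound: ", reg$compound)
    if (reg$dose == 0) next
    tms <- dose_times(reg)
    if (max(tms) > t_end) stop("t_end does not cover all doses")
    rec <- compounds[[ci]]
    s <- 2L + (ci - 1L) * .NSCPD
    if (reg$route == "oral") {
      ev[[length(ev) + 1L]] <- data.frame(var = s + 1L, time = tms,
                                          value = rec$fa * reg$dose,
                                          method = "add")
    } else { # iv-bolus into venous blood
      ev[[length(ev) + 1L]] <- data.frame(
        var = s + 14L, time = tms,
        value = reg$dose / phys$tissue_volumes[["venous_blood"]],
        method = "add")
    }
  }
  nstate <- 2L + length(compounds) * .NSCPD
  y0 <- setNames(numeric(nstate), .state_names(compounds))
  y0[1:2] <- 1
  events <- if (length(ev)) do.call(rbind, ev) else NULL
  if (!is.null(events)) {
    at0 <- events$time <= 0
    if (any(at0)) {
      for (k in which(at0)) y0[events$var[k]] <- y0[events$var[k]] + events$value[k]
      events <- events[!at0, , drop = FALSE]
      if (!nrow(events)) events <- NULL
    }
  }

  times <- seq(0, t_end, by = opts$dt_out)
  if (!is.null(events)) {
    times <- sort(unique(round(c(times, events$time), 9)))
    events <- events[order(events$time), , drop = FALSE]
  }

  parms <- .pbpk_parms(compounds, kpps, phys)
  out <- deSolve::lsoda(
    y = y0, times = times, func = "pbpk_derivs", parms = parms,
    dllname = "pbpkddi", initfunc = "pbpk_init",
    rtol = opts$rtol, atol = opts$atol, maxsteps = opts$maxsteps,
    events = if (!is.null(events)) list(data = events) else NULL)
  diag <- attributes(out)$istate
  if (!is.null(diag) && diag[1] < 0)
    stop("ODE solver failed (istate ", diag[1], ") for ",
         paste(cnames, collapse = "+"))
  y <- unclass(out)[, -1, drop = FALSE]
  colnames(y) <- .state_names(compounds)
  if (min(y) < -1e3 * opts$atol)
    stop("negative state encountered (min ", format(min(y)),
         "); solver diagnostics suggest tightening tolerances")

  plasma <- sapply(seq_along(compounds), function(i) {
    s <- 2L + (i - 1L) * .NSCPD
    y[, s + 14L] / compounds[[i]]$bp_ratio * 1000  # venous plasma ng/mL
  })
  plasma <- matrix(plasma, ncol = length(compounds),
                   dimnames = list(NULL, cnames))

  structure(list(
    time = unclass(out)[, 1], plasma = plasma,
    enzyme = y[, 1:2, drop = FALSE], state = y,
    compounds = compounds, kpps = kpps, regimens = regimens,
    phys = phys, opts = opts,
    dosing = if (!is.null(events)) events else
      data.frame(var = integer(), time = numeric(), value = numeric(),
                 method = character())
  ), class = "pbpk_sim")
}

#' @export
print.pbpk_sim <- function(x, ...) {
  cat("<pbpk_sim> ", paste(colnames(x$plasma), collapse = " + "),
      "; t in [0, ", max(x$time), "] h, ", length(x$time), " points\n",
      sep = "")
  invisible(x)
}

#' Tidy concentration data from a simulation
#'
#' @param x a `pbpk_sim`.
#' @param row.names,optional,... ignored (S3 signature).
#' @return data.frame with `time_h`, `compound`, `conc_ng_per_ml`.
#' @export
as.data.frame.pbpk_sim <- function(x, row.names = NULL, optional = FALSE, ...) {
  do.call(rbind, lapply(colnames(x$plasma), function(cn) {
    data.frame(time_h = x$time, compound = cn,
               conc_ng_per_ml = x$plasma[, cn], row.names = NULL)
  }))
}

#' Mass-balance ledger of a simulation
#'
#' At every output time, the absorbed/injected dose must equal the body
#' burden plus everything metabolized and excreted:
#' `fa * oral + iv = depot + sum_t V_t C_t + blood + gut met + hepatic CYP
#' met + additional met + renal`.
#'
#' @param sim a `pbpk_sim`.
#' @return data.frame per compound and time with `input_mg`, `accounted_mg`
#'   and `rel_error` (relative to input; 0 where nothing dosed yet).
#' @export
mass_balance <- function(sim) {
  phys <- sim$phys
  vols <- c(phys$tissue_volumes[.TISSUES],
            arterial = unname(phys$tissue_volumes[["arterial_blood"]]),
            venous = unname(phys$tissue_volumes[["venous_blood"]]))
  cnames <- colnames(sim$plasma)
  out <- list()
  for (i in seq_along(cnames)) {
    s <- 2L + (i - 1L) * .NSCPD
    rec <- sim$compounds[[i]]
    # cumulative dosed input at each output time
    input <- numeric(length(sim$time))
    for (reg in sim$regimens) {
      if (reg$compound != cnames[i] || reg$dose == 0) next
      per <- if (reg$route == "oral") rec$fa * reg$dose else reg$dose
      for (tt in dose_times(reg)) {
        # solver output at an event time is the pre-event state; only the
        # initial dose (folded into y0) is visible at its own time point
        given <- if (tt <= sim$time[1] + 1e-9) sim$time >= tt - 1e-9
                 else sim$time > tt + 1e-9
        input <- input + per * given
      }
    }
    conc <- sim$state[, s + 2L:14L, drop = FALSE]   # 11 tissues + art + ven
    body <- as.vector(conc %*% vols) + sim$state[, s + 1L]
    accounted <- body + rowSums(sim$state[, s + 15L:18L, drop = FALSE])
    rel <- ifelse(input > 0, (accounted - input) / input, 0)
    out[[i]] <- data.frame(compound = cnames[i], time_h = sim$time,
                           input_mg = input, accounted_mg = accounted,
                           rel_error = rel)
  }
  do.call(rbind, out)
}

#' Closed-form enzyme steady state under constant exposure
#'
#' Balance of zero-order synthesis (possibly induced), first-order
#' degradation and mechanism-based inactivation:
#' `E_ss = kdeg * (1 + ind) / (kdeg + kinact * Iu / (Kapp + Iu))`.
#'
#' @param kdeg enzyme degradation rate constant (1/h).
#' @param kinact maximal inactivation rate (1/h).
#' @param iu unbound inhibitor concentration (uM).
#' @param kapp inhibitor concentration at half-maximal inactivation (uM).
#' @param ind_term induction term (fold increase of synthesis above 1).
#' @return steady-state active-enzyme fraction of baseline.
#' @export
#' @examples
#' enzyme_steady_state(0.0193, 0.17, iu = 1e9, kapp = 9.66) # deep TDI limit
enzyme_steady_state <- function(kdeg, kinact, iu, kapp, ind_term = 0) {
  stopifnot(kdeg > 0, kinact >= 0, iu >= 0, kapp >= 0, ind_term >= 0)
  kdeg * (1 + ind_term) / (kdeg + kinact * iu / (kapp + iu))
}

#' Strip time-dependent-inactivation parameters from a record
#'
#' Used by the first calibration step, which excludes auto-inactivation.
#'
#' @param rec a `compound_record`.
#' @return the record with `kinact` removed.
#' @export
without_tdi <- function(rec) {
  if (!is.null(rec$interaction)) {
    rec$interaction$kinact <- NULL
    rec$interaction$kapp <- NULL
    if (!length(setdiff(names(rec$interaction), "fu_mic")))
      rec$interaction <- NULL
  }
  rec
}

.apply_subject_multipliers <- function(rec, phys) {
  mult <- attr(phys, "param_multipliers")
  if (is.null(mult) || !length(mult)) return(rec)
  if (!is.null(mult[["fa"]])) rec$fa <- min(rec$fa * mult[["fa"]], 1)
  if (!is.null(mult[["ka"]])) rec$ka <- rec$ka * mult[["ka"]]
  if (!is.null(mult[["cl_renal"]])) rec$cl_renal <- rec$cl_renal * mult[["cl_renal"]]
  if (!is.null(mult[["cl_additional"]]))
    rec$cl_additional <- rec$cl_additional * mult[["cl_additional"]]
  rec
}

#' Simulate a paired virtual trial
#'
#' For every sampled subject, runs two simulations sharing the identical
#' physiology draw: the victim alone, and the victim co-dosed with the
#' perpetrator (paired design). Deterministic under the scenario seed.
#'
#' @param config a [scenario_config()].
#' @param opts solver options.
#' @return list with `subjects` (per subject: `trial`, `id`, `alone`,
#'   `combo` simulations) and the `config`.
#' @export
simulate_trial <- function(config, opts = solver_options()) {
  stopifnot(inherits(config, "scenario_config"))
  base <- default_healthy_volunteer()
  victim <- config$victim$record
  perp <- if (!is.null(config$perpetrator)) config$perpetrator$record
  n_total <- config$trial$n_trials * config$trial$n_subjects
  pop <- sample_population(base, n_total,
                           variability_spec(config$trial$cv_map,
                                            seed = config$trial$seed))
  kpp_v <- scaled_kp_set(victim, base)
  kpp_p <- if (!is.null(perp)) scaled_kp_set(perp, base)
  has_perp <- !is.null(perp) && config$perpetrator$regimen$dose > 0

  subjects <- vector("list", n_total)
  for (i in seq_len(n_total)) {
    phys_i <- pop[[i]]
    vic_i <- .apply_subject_multipliers(victim, phys_i)
    alone <- simulate_subject(list(vic_i), list(config$victim$regimen),
                              phys = phys_i, t_end = config$t_end,
                              kpps = list(kpp_v), opts = opts)
    combo <- if (has_perp) {
      simulate_subject(list(vic_i, perp),
                       list(config$victim$regimen, config$perpetrator$regimen),
                       phys = phys_i, t_end = config$t_end,
                       kpps = list(kpp_v, kpp_p), opts = opts)
    } else alone
    subjects[[i]] <- list(trial = (i - 1L) %/% config$trial$n_subjects + 1L,
                          id = i, alone = alone, combo = combo)
  }
  list(subjects = subjects, config = config)
}

#' Export simulated concentrations as tidy CSV with a JSON run manifest
#'
#' @param trial result of [simulate_trial()].
#' @param file CSV output path; a `<file>.manifest.json` is written next to
#'   it with the seed, tolerances and scenario description.
#' @return `file`, invisibly.
#' @export
export_trial_csv <- function(trial, file) {
  rows <- lapply(trial$subjects, function(su) {
    do.call(rbind, lapply(c("alone", "combo"), function(arm) {
      df <- as.data.frame(su[[arm]])
      df$subject <- su$id; df$arm <- arm
      df[, c("subject", "arm", "compound", "time_h", "conc_ng_per_ml")]
    }))
  })
  write.csv(do.call(rbind, rows), file, row.names = FALSE)
  manifest <- list(
    scenario = trial$config$name,
    seed = trial$config$trial$seed,
    n_trials = trial$config$trial$n_trials,
    n_subjects = trial$config$trial$n_subjects,
    rtol = trial$subjects[[1]]$alone$opts$rtol,
    atol = trial$subjects[[1]]$alone$opts$atol)
  jsonlite::write_json(manifest, paste0(file, ".manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(file)
}
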