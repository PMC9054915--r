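#' Construct a compound parameter record
#'
#' Bundles the drug-specific inputs of the PBPK model: physicochemistry
#' (partitioning), a first-order absorption model with a nominal gut flow,
#' recombinant-CYP3A4 enzyme kinetics, additional (non-CYP) hepatic and renal
#' clearance, and CYP3A4 interaction parameters (competitive inhibition,
#' mechanism-based inactivation, induction).
#'
#' @param name compound name.
#' @param mw molecular weight (g/mol).
#' @param logp octanol:water log partition coefficient.
#' @param compound_type one of `"monoprotic_base"`, `"diprotic_base"`,
#'   `"acid"`, `"neutral"`.
#' @param pka1,pka2 acid dissociation constants (pka2 only for diprotic).
#' @param bp_ratio blood:plasma concentration ratio.
#' @param fu_plasma fraction unbound in plasma.
#' @param fa fraction of the oral dose absorbed into the gut wall.
#' @param ka first-order absorption rate constant (1/h).
#' @param fu_gut unbound fraction in enterocytes.
#' @param q_gut nominal gut flow of the first-pass model (L/h).
#' @param peff,papp_mdck,perm_scalar optional permeability metadata
#'   (1e-4 cm/s, 1e-6 cm/s, unitless).
#' @param vss_target optional observed steady-state volume of distribution
#'   (L/kg) used to resolve the Kp scalar.
#' @param kp_scalar nominal uniform Kp multiplier.
#' @param cyp3a4 `NULL` or list with `vmax` (pmol/min/pmol), `km` (uM, unbound
#'   with `fu_mic` 1), `fu_mic`.
#' @param cl_additional additional intrinsic hepatic clearance acting on the
#'   unbound liver water concentration (L/h).
#' @param cl_renal renal clearance referenced to venous plasma (L/h).
#' @param interaction `NULL` or list with any of `ki` (uM), `kapp` (uM),
#'   `kinact` (1/h), `ind_max` (fold), `ind_c50` (uM), `fu_mic`.
#' @return an object of class `compound_record`.
#' @export
compound_record <- function(name, mw, logp, compound_type, pka1 = NA,
                            pka2 = NA, bp_ratio, fu_plasma, fa, ka,
                            fu_gut = 1, q_gut, peff = NA, papp_mdck = NA,
                            perm_scalar = NA, vss_target = NA, kp_scalar = 1,
                            cyp3a4 = NULL, cl_additional = 0, cl_renal = 0,
                            interaction = NULL) {
  rec <- structure(list(
    name = name, mw = mw, logp = logp, compound_type = compound_type,
    pka1 = pka1, pka2 = pka2, bp_ratio = bp_ratio, fu_plasma = fu_plasma,
    fa = fa, ka = ka, fu_gut = fu_gut, q_gut = q_gut, peff = peff,
    papp_mdck = papp_mdck, perm_scalar = perm_scalar,
    vss_target = vss_target, kp_scalar = kp_scalar, cyp3a4 = cyp3a4,
    cl_additional = cl_additional, cl_renal = cl_renal,
    interaction = interaction
  ), class = "compound_record")
  validate_compound(rec)
}

#' Validate a compound record
#'
#' @param rec a `compound_record`.
#' @return `rec` invisibly-validated (returned visibly for chaining).
#' @export
validate_compound <- function(rec) {
  stopifnot(inherits(rec, "compound_record"))
  chk <- function(ok, msg) if (!isTRUE(ok)) stop(rec$name, ": ", msg, call. = FALSE)
  chk(is.character(rec$name) && nzchar(rec$name), "name required")
  chk(rec$mw > 0, "mw must be > 0")
  chk(rec$compound_type %in% c("monoprotic_base", "diprotic_base", "acid",
                               "neutral"),
      "unknown compound_type")
  if (rec$compound_type != "neutral")
    chk(is.finite(rec$pka1), "pka1 required for ionizable compound")
  if (rec$compound_type == "diprotic_base")
    chk(is.finite(rec$pka2), "pka2 required for diprotic base")
  for (f in c("fu_plasma", "fa", "fu_gut"))
    chk(rec[[f]] >= 0 && rec[[f]] <= 1, paste(f, "must be in [0,1]"))
  chk(rec$bp_ratio > 0, "bp_ratio must be > 0")
  chk(rec$ka > 0, "ka must be > 0")
  chk(rec$q_gut > 0, "q_gut must be > 0")
  chk(rec$kp_scalar > 0, "kp_scalar must be > 0")
  chk(rec$cl_additional >= 0, "cl_additional must be >= 0")
  chk(rec$cl_renal >= 0, "cl_renal must be >= 0")
  if (!is.null(rec$cyp3a4)) {
    chk(rec$cyp3a4$vmax >= 0, "cyp3a4 vmax must be >= 0")
    chk(rec$cyp3a4$km > 0, "cyp3a4 km must be > 0")
    chk(rec$cyp3a4$fu_mic > 0 && rec$cyp3a4$fu_mic <= 1,
        "cyp3a4 fu_mic must be in (0,1]")
  }
  if (!is.null(rec$interaction)) {
    it <- rec$interaction
    for (f in c("ki", "kapp", "ind_c50"))
      if (!is.null(it[[f]])) chk(it[[f]] > 0, paste("interaction", f, "must be > 0"))
    if (!is.null(it$kinact)) chk(it$kinact >= 0, "kinact must be >= 0")
    if (!is.null(it$ind_max)) chk(it$ind_max >= 0, "ind_max must be >= 0")
  }
  rec
}

.num_or_na <- function(x) if (is.null(x)) NA_real_ else x

#' Read a compound record from a structured text fixture
#'
#' Fixture files are flat `key value unit` triples (one per line, `#`
#' comments); see `inst/extdata/compounds/` for the shipped records.
#'
#' @param file path to the fixture file.
#' @return a validated `compound_record`.
#' @export
read_compound_file <- function(file) {
  kv <- .read_kv_file(file)
  g <- function(key, default = NULL) {
    v <- kv[[key]]
    if (is.null(v)) default else v
  }
  cyp <- NULL
  if (!is.null(kv[["cyp3a4.vmax"]])) {
    cyp <- list(vmax = g("cyp3a4.vmax"), km = g("cyp3a4.km"),
                fu_mic = g("cyp3a4.fu_mic", 1))
  }
  inter <- NULL
  inter_keys <- c(ki = "interaction.ki", kapp = "interaction.kapp",
                  kinact = "interaction.kinact", ind_max = "interaction.ind_max",
                  ind_c50 = "interaction.ind_c50", fu_mic = "interaction.fu_mic")
  if (any(names(kv) %in% inter_keys)) {
    inter <- lapply(inter_keys, function(k) kv[[k]])
    inter <- inter[!vapply(inter, is.null, TRUE)]
  }
  compound_record(
    name = g("name"), mw = g("mw"), logp = g("logp"),
    compound_type = g("compound_type"),
    pka1 = .num_or_na(g("pka1")), pka2 = .num_or_na(g("pka2")),
    bp_ratio = g("bp_ratio"), fu_plasma = g("fu_plasma"),
    fa = g("fa"), ka = g("ka"), fu_gut = g("fu_gut", 1), q_gut = g("q_gut"),
    peff = .num_or_na(g("peff")), papp_mdck = .num_or_na(g("papp_mdck")),
    perm_scalar = .num_or_na(g("perm_scalar")),
    vss_target = .num_or_na(g("vss_target")), kp_scalar = g("kp_scalar", 1),
    cyp3a4 = cyp, cl_additional = g("cl_additional", 0),
    cl_renal = g("cl_renal", 0), interaction = inter
  )
}

#' Write a compound record to a structured text file
#'
#' @param rec a `compound_record`.
#' @param file output path.
#' @return `file`, invisibly.
#' @export
write_compound_file <- function(rec, file) {
  validate_compound(rec)
  ln <- c(
    paste("name", rec$name),
    paste("mw", rec$mw, "g/mol"),
    paste("logp", rec$logp, "-"),
    paste("compound_type", rec$compound_type))
  add <- function(key, val, unit) {
    if (!is.null(val) && length(val) == 1 && is.finite(val))
      ln <<- c(ln, paste(key, val, unit))
  }
  add("pka1", rec$pka1, "-"); add("pka2", rec$pka2, "-")
  add("bp_ratio", rec$bp_ratio, "-")
  add("fu_plasma", rec$fu_plasma, "fraction")
  add("fa", rec$fa, "fraction"); add("ka", rec$ka, "1/h")
  add("fu_gut", rec$fu_gut, "fraction"); add("q_gut", rec$q_gut, "L/h")
  add("papp_mdck", rec$papp_mdck, "1e-6cm/s")
  add("perm_scalar", rec$perm_scalar, "-")
  add("peff", rec$peff, "1e-4cm/s")
  add("vss_target", rec$vss_target, "L/kg")
  add("kp_scalar", rec$kp_scalar, "-")
  if (!is.null(rec$cyp3a4)) {
    add("cyp3a4.vmax", rec$cyp3a4$vmax, "pmol/min/pmol")
    add("cyp3a4.km", rec$cyp3a4$km, "uM")
    add("cyp3a4.fu_mic", rec$cyp3a4$fu_mic, "fraction")
  }
  add("cl_additional", rec$cl_additional, "L/h")
  add("cl_renal", rec$cl_renal, "L/h")
  if (!is.null(rec$interaction)) {
    it <- rec$interaction
    add("interaction.ki", it$ki, "uM")
    add("interaction.kapp", it$kapp, "uM")
    add("interaction.kinact", it$kinact, "1/h")
    add("interaction.ind_max", it$ind_max, "fold")
    add("interaction.ind_c50", it$ind_c50, "uM")
    add("interaction.fu_mic", it$fu_mic, "fraction")
  }
  writeLines(ln, file)
  invisible(file)
}

#' The final ipatasertib model record
#'
#' The published final-model parameter set: diprotic base, MW 458, logP 3,
#' B/P 1.43, fu 0.63; first-order absorption (fa 0.76, ka 0.76 1/h, Qgut
#' 9.28 L/h); full-PBPK distribution to a Vss of 39.13 L/kg; saturable
#' recombinant-CYP3A4 elimination (Vmax 0.135 pmol/min/pmol, Km 0.195 uM)
#' plus additional hepatic clearance 2.7 L/h and renal clearance 19.3 L/h;
#' competitive inhibition Ki 4.4 uM and time-dependent inactivation
#' (Kapp 9.66 uM, kinact 0.17 1/h).
#'
#' @return a `compound_record`.
#' @export
#' @examples
#' ipa <- ipatasertib_final()
#' um_to_ngml(ipa$cyp3a4$km, ipa$mw) # Km on the mass scale
ipatasertib_final <- function() {
  if (is.null(.pkg_cache$ipatasertib))
    .pkg_cache$ipatasertib <-
      read_compound_file(.extdata("compounds", "ipatasertib.txt"))
  .pkg_cache$ipatasertib
}

#' Load a perpetrator or probe-substrate fixture record
#'
#' Versioned records for the interaction partners used by the simulation
#' scenarios. These parameters are assembled from the published compound
#' literature (provenance noted inside each fixture file) and are gated by
#' [qualify_fixture()] against their interaction-class envelopes.
#'
#' @param name one of `"itraconazole"`, `"erythromycin"`, `"diltiazem"`,
#'   `"fluvoxamine"`, `"rifampin"`, `"efavirenz"`, `"midazolam"`.
#' @return a `compound_record`.
#' @export
perpetrator_fixture <- function(name) {
  avail <- c("itraconazole", "erythromycin", "diltiazem", "fluvoxamine",
             "rifampin", "efavirenz", "midazolam")
  if (!is.character(name) || length(name) != 1 || !(name %in% avail))
    stop("unknown fixture '", paste(name, collapse = ","),
         "'; available: ", paste(avail, collapse = ", "), call. = FALSE)
  key <- paste0("cpd_", name)
  if (is.null(.pkg_cache[[key]]))
    .pkg_cache[[key]] <-
      read_compound_file(.extdata("compounds", paste0(name, ".txt")))
  .pkg_cache[[key]]
}

#' Define a dosing regimen
#'
#' @param compound compound name the regimen refers to.
#' @param dose dose amount (mg).
#' @param route `"oral"` or `"iv-bolus"` (`"iv-infusion"` is part of the
#'   schema but cannot be integrated without a duration and is rejected).
#' @param interval dosing interval (h); required when `n_doses > 1`.
#' @param n_doses number of doses.
#' @param start_time time of the first dose (h).
#' @return an object of class `dose_regimen`.
#' @export
#' @examples
#' dose_regimen("ipatasertib", 400, "oral", interval = 24, n_doses = 21)
dose_regimen <- function(compound, dose, route = "oral", interval = 24,
                         n_doses = 1, start_time = 0) {
  stopifnot(dose >= 0, n_doses >= 1, start_time >= 0)
  route <- match.arg(route, c("oral", "iv-bolus", "iv-infusion"))
  if (route == "iv-infusion")
    stop("iv-infusion regimens carry no duration field and are not supported")
  if (n_doses > 1 && interval <= 0) stop("interval must be > 0 for multiple doses")
  structure(list(compound = compound, dose = dose, route = route,
                 interval = interval, n_doses = as.integer(n_doses),
                 start_time = start_time),
            class = "dose_regimen")
}

dose_times <- function(reg) reg$start_time + (seq_len(reg$n_doses) - 1) * reg$interval

#' Hepatic fraction metabolized by CYP3A4 at trace concentration
#'
#' Shares of linearized intrinsic clearance at the liver: CYP3A4
#' (`Vmax_total/Km`) versus the additional (non-CYP) intrinsic clearance,
#' combined with renal clearance through the well-stirred model to a whole-
#' body fraction metabolized by CYP3A4.
#'
#' @param rec a `compound_record`.
#' @param phys a `system_physiology`.
#' @return list with `fm_hepatic` (CYP share of hepatic intrinsic clearance)
#'   and `fm_total` (CYP share of total plasma clearance).
#' @export
fm_cyp3a4 <- function(rec, phys = default_healthy_volunteer()) {
  clint_cyp <- 0
  if (!is.null(rec$cyp3a4) && rec$cyp3a4$vmax > 0) {
    vmax_tot_umolh <- rec$cyp3a4$vmax * hepatic_cyp3a4_total(phys) * 60 / 1e6
    clint_cyp <- vmax_tot_umolh / rec$cyp3a4$km      # L/h
  }
  clint_tot <- clint_cyp + rec$cl_additional
  # engine convention: metabolism is driven by fu_plasma times the emergent
  # blood concentration, so fu applies to blood directly here
  fub <- rec$fu_plasma
  qh <- sum(phys$tissue_blood_flows[c("liver", "gut", "spleen")])
  clh_b <- qh * fub * clint_tot / (qh + fub * clint_tot)
  clh_p <- clh_b * rec$bp_ratio
  cl_tot <- clh_p + rec$cl_renal
  fm_hep <- if (clint_tot > 0) clint_cyp / clint_tot else 0
  list(fm_hepatic = fm_hep,
       fm_total = if (cl_tot > 0) fm_hep * clh_p / cl_tot else 0)
}

#' @export
print.compound_record <- function(x, ...) {
  cat("<compound_record> ", x$name, " (", x$compound_type, ", MW ", x$mw,
      ")\n", sep = "")
  if (!is.null(x$cyp3a4))
    cat("  CYP3A4 Vmax ", x$cyp3a4$vmax, " pmol/min/pmol, Km ",
        x$cyp3a4$km, " uM\n", sep = "")
  cat("  CL_additional ", x$cl_additional, " L/h, CL_R ", x$cl_renal,
      " L/h\n", sep = "")
  invisible(x)
}
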