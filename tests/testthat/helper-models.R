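# shared helpers: fast solver settings and small purpose-built compounds

quick_opts <- solver_options(dt_out = 0.5)

# a compound with purely linear elimination (no CYP3A4 pathway): closed-form
# oracles for clearance, bioavailability and superposition apply exactly
linear_probe <- function(cl_additional = 100, cl_renal = 5, ka = 1,
                         fa = 0.8, q_gut = 10) {
  compound_record(
    name = "probe", mw = 400, logp = 2, compound_type = "monoprotic_base",
    pka1 = 8.5, bp_ratio = 1, fu_plasma = 0.2, fa = fa, ka = ka,
    fu_gut = 1, q_gut = q_gut, vss_target = 2, kp_scalar = 1,
    cyp3a4 = NULL, cl_additional = cl_additional, cl_renal = cl_renal)
}

# ipatasertib-like record pushed into the linear CYP limit: Km scaled up with
# Vmax/Km held fixed, so gut escape reduces to the static Qgut formula and
# hepatic clearance to the well-stirred composite
linear_limit_ipa <- function(scale = 1e6) {
  rec <- ipatasertib_final()
  rec$cyp3a4$km <- rec$cyp3a4$km * scale
  rec$cyp3a4$vmax <- rec$cyp3a4$vmax * scale
  rec <- without_tdi(rec)
  rec$interaction <- NULL
  rec
}

# algebraic composites for a linear compound against the mean physiology:
# well-stirred hepatic clearance, static gut escape, oral bioavailability.
# The engine drives hepatic elimination with fu_plasma times the emergent
# liver blood concentration, so the effective unbound fraction in the
# well-stirred composite applies to blood.
linear_composites <- function(rec, phys = default_healthy_volunteer()) {
  clint_cyp <- 0
  if (!is.null(rec$cyp3a4) && rec$cyp3a4$vmax > 0)
    clint_cyp <- rec$cyp3a4$vmax * hepatic_cyp3a4_total(phys) * 60 / 1e6 /
      rec$cyp3a4$km
  clint <- clint_cyp + rec$cl_additional
  fub <- rec$fu_plasma
  qh <- sum(phys$tissue_blood_flows[c("liver", "gut", "spleen")])
  clh_b <- qh * fub * clint / (qh + fub * clint)
  fh <- qh / (qh + fub * clint)
  clint_gut <- if (!is.null(rec$cyp3a4) && rec$cyp3a4$vmax > 0)
    rec$cyp3a4$vmax * phys$cyp3a4_gut_total * 1000 * 60 / 1e6 / rec$cyp3a4$km
  else 0
  fg <- rec$q_gut / (rec$q_gut + rec$fu_gut * clint_gut)
  cl_p <- clh_b * rec$bp_ratio + rec$cl_renal
  list(cl_plasma = cl_p, fh = fh, fg = fg, f_oral = rec$fa * fg * fh)
}

no_variability <- function() {
  cv <- default_cv_map()
  cv[] <- 0
  cv
}
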