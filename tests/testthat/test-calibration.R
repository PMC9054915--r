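test_that("retrograde calculation round-trips through the well-stirred model", {
  phys <- default_healthy_volunteer()
  for (clint in c(0.1, 0.692, 5)) {
    cl_iv <- forward_cl_iv(clint, cl_renal = 19.3, cl_additional = 2.7,
                           fu = 0.63, bp = 1.43, phys)
    back <- retrograde_clint(cl_iv, 19.3, 2.7, 0.63, 1.43, phys)
    expect_equal(back, clint, tolerance = 1e-9)
  }
  # Vmax = CLint x Km reproduces the published pairing
  expect_equal(retrograde_vmax(0.692, 0.195), 0.135, tolerance = 1e-3)
  expect_equal(retrograde_vmax(3.3, 1), 3.3)
  expect_equal(retrograde_vmax(0.5, 10), 10 * retrograde_vmax(0.5, 1))
})

test_that("retrograde limiting and error cases are explicit", {
  phys <- default_healthy_volunteer()
  # cl_additional absorbing (almost) the whole hepatic clearance -> CYP ~ 0
  cl_iv <- forward_cl_iv(1e-6, cl_renal = 19.3, cl_additional = 2.7,
                         fu = 0.63, bp = 1.43, phys)
  expect_lt(retrograde_clint(cl_iv, 19.3, 2.7, 0.63, 1.43, phys), 1e-5)
  expect_error(retrograde_clint(19.3, 19.3, 0, 0.63, 1.43, phys), "exceed")
  qh <- sum(phys$tissue_blood_flows[c("liver", "gut", "spleen")])
  expect_error(retrograde_clint(qh * 1.43 + 20, 19.3, 0, 0.63, 1.43, phys),
               "unphysical")
})

test_that("step-1 returns immediately when the anchors come from the default start", {
  # self-consistent targets generated from the initial-guess parameter pair:
  # the residual at iteration zero is (numerically) null and the fit must
  # return that pair
  base <- ipatasertib_final()
  km <- base$cyp3a4$km
  v0 <- retrograde_vmax(0.692, km)
  ev <- pbpkddi:::.step1_eval(v0, max(base$cl_additional, 0.5), km, base,
                              solver_options(dt_out = 0.5))
  tg <- calibration_targets(itz_auc_ratio = ev$ratio, ipa_auc_ref = ev$auc)
  t0 <- Sys.time()
  cand <- fit_step1_itraconazole(km, targets = tg, base = base)
  expect_lt(as.numeric(difftime(Sys.time(), t0, units = "secs")), 30)
  expect_equal(cand$vmax, v0, tolerance = 1e-6)
  expect_equal(cand$cl_additional, max(base$cl_additional, 0.5),
               tolerance = 1e-6)
})

test_that("step-2 resolves the kinact floor and rejects unreachable targets", {
  cand <- candidate_model(km = 0.195, vmax = 0.135, cl_additional = 2.7,
                          provenance = "step1-itraconazole")
  # the ratio at kinact = 0 (competitive inhibition only) is its own target
  rec0 <- apply_candidate(cand, tdi = FALSE)
  r0 <- generate_ddi_anchor(rec0, "midazolam_600mg")
  floor_fit <- fit_step2_kinact(cand, calibration_targets(mdz_auc_ratio = r0))
  expect_equal(floor_fit$kinact, 0)
  expect_error(
    fit_step2_kinact(cand, calibration_targets(mdz_auc_ratio = r0 * 0.5)),
    "floor")
  expect_error(
    fit_step2_kinact(cand, calibration_targets(mdz_auc_ratio = 50)),
    "achievable")
})

test_that("candidate application controls the TDI switch", {
  cand <- candidate_model(km = 1.95, vmax = 1, cl_additional = 11.8,
                          kinact = 0.33)
  with_tdi <- apply_candidate(cand, tdi = TRUE)
  expect_equal(with_tdi$cyp3a4$km, 1.95)
  expect_equal(with_tdi$interaction$kinact, 0.33)
  no_tdi <- apply_candidate(cand, tdi = FALSE)
  expect_null(no_tdi$interaction$kinact)
  expect_false(is.null(no_tdi$interaction$ki))  # competitive survives
})

test_that("final-model selection prefers the flattest profile for flat data", {
  # two synthetic candidates: a saturable one and an (almost) linear one;
  # against dose-independent observed CL/F the linear candidate must win
  flat_obs <- data.frame(dose = rep(c(25, 100, 400), each = 2),
                         phase = rep(c("single", "steady_state"), 3),
                         cl_over_f = 700)
  sat <- candidate_model(km = 0.195, vmax = 0.135, cl_additional = 2.7,
                         kinact = 0)
  lin <- candidate_model(km = 1950, vmax = 1350, cl_additional = 2.7,
                         kinact = 0)
  sel <- select_final_model(list(sat, lin), flat_obs,
                            opts = solver_options(dt_out = 1))
  expect_equal(sel$km, 1950)
  objs <- attr(sel, "objectives")
  expect_lt(objs$objective[objs$km == 1950], objs$objective[objs$km == 0.195])
})
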