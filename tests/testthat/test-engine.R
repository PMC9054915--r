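test_that("zero dose yields identically zero concentrations", {
  sim <- simulate_subject(linear_probe(),
                          dose_regimen("probe", 0, "oral"),
                          t_end = 24, opts = quick_opts)
  expect_true(all(sim$plasma == 0))
  expect_true(all(sim$enzyme == 1))
})

test_that("IV bolus AUC matches Dose/CL for linear elimination", {
  rec <- linear_probe(cl_additional = 100, cl_renal = 5)
  comp <- linear_composites(rec)
  # dense early grid: the venous mixing spike after a bolus is fast and the
  # trapezoid must resolve it for the closed-form comparison
  sim <- simulate_subject(rec, dose_regimen("probe", 0.08, "iv-bolus"),
                          t_end = 96, opts = solver_options(dt_out = 0.005))
  ns <- nca_single(sim$time, sim$plasma[, "probe"], dose = 0.08)
  expect_equal(ns$cl_over_f, comp$cl_plasma, tolerance = 0.005)
})

test_that("the linear CYP limit reproduces static Qgut and well-stirred composites", {
  rec <- linear_limit_ipa()
  comp <- linear_composites(rec)
  # oral AUC = F * Dose / CL in the linear limit
  sim <- simulate_subject(rec, dose_regimen("ipatasertib", 100, "oral"),
                          t_end = 480, opts = quick_opts)
  ns <- nca_single(sim$time, sim$plasma[, "ipatasertib"], dose = 100)
  auc_pred <- comp$f_oral * 100 * 1e6 / comp$cl_plasma / 1000
  expect_equal(ns$auc_0_inf, auc_pred, tolerance = 0.01)
})

test_that("superposition holds under linear kinetics", {
  rec <- linear_probe(cl_additional = 300, cl_renal = 2)
  single <- simulate_subject(rec, dose_regimen("probe", 50, "oral"),
                             t_end = 240, opts = quick_opts)
  auc_inf <- nca_single(single$time, single$plasma[, 1], dose = 50)$auc_0_inf
  multi <- simulate_subject(rec,
                            dose_regimen("probe", 50, "oral", 24, 10),
                            t_end = 264, opts = quick_opts)
  keep <- multi$time >= 216
  auc_tau <- nca_single(multi$time[keep] - 216, multi$plasma[keep, 1],
                        tau = 24)$auc_tau
  expect_equal(auc_tau, auc_inf, tolerance = 0.01)
})

test_that("exposure is more than dose-proportional for the saturable record", {
  ipa <- ipatasertib_final()
  lo <- simulate_subject(ipa, dose_regimen("ipatasertib", 25, "oral"),
                         t_end = 192, opts = quick_opts)
  hi <- simulate_subject(ipa, dose_regimen("ipatasertib", 400, "oral"),
                         t_end = 192, opts = quick_opts)
  auc_lo <- nca_single(lo$time, lo$plasma[, 1], dose = 25)$auc_0_inf
  auc_hi <- nca_single(hi$time, hi$plasma[, 1], dose = 400)$auc_0_inf
  expect_gt(auc_hi / 400, auc_lo / 25)
})

test_that("mass balance holds to ten times the solver tolerance", {
  ipa <- ipatasertib_final()
  itz <- perpetrator_fixture("itraconazole")
  sim <- simulate_subject(
    list(ipa, itz),
    list(dose_regimen("ipatasertib", 400, "oral", 24, 5),
         dose_regimen("itraconazole", 200, "oral", 24, 5)),
    t_end = 144, opts = quick_opts)
  mb <- mass_balance(sim)
  expect_lt(max(abs(mb$rel_error)), 10 * sim$opts$rtol)
})

test_that("enzyme turnover ODE agrees with the closed-form steady state", {
  # independent ODE oracle at constant unbound inhibitor concentration
  kdeg <- 0.0193; kinact <- 0.17; kapp <- 9.66
  for (iu in c(0.5, 5, 50)) {
    f <- function(t, y, p) list(kdeg - kdeg * y - y * kinact * iu / (kapp + iu))
    tgrid <- seq(0, 10 * log(2) / kdeg, length.out = 200)
    num <- deSolve::lsoda(c(E = 1), tgrid, f, NULL, rtol = 1e-10,
                          atol = 1e-12)
    expect_equal(unname(num[nrow(num), "E"]),
                 enzyme_steady_state(kdeg, kinact, iu, kapp),
                 tolerance = 1e-4)
  }
  expect_equal(enzyme_steady_state(0.0193, 0.17, 0, 9.66), 1)
  expect_equal(enzyme_steady_state(0.0193, 0.17, 1e12, 9.66),
               0.0193 / (0.0193 + 0.17), tolerance = 1e-6)
})

test_that("competitive inhibition and induction move victim exposure monotonically", {
  ipa <- ipatasertib_final()
  auc_with <- function(perp_name, dose) {
    perp <- perpetrator_fixture(perp_name)
    sim <- simulate_subject(
      list(ipa, perp),
      list(dose_regimen("ipatasertib", 100, "oral", start_time = 96),
           dose_regimen(perp_name, dose, "oral", 24, 9)),
      t_end = 240, opts = quick_opts)
    keep <- sim$time >= 96
    nca_single(sim$time[keep] - 96, sim$plasma[keep, "ipatasertib"],
               tau = 24)$auc_tau
  }
  inh <- vapply(c(0, 50, 200), function(d) auc_with("itraconazole", d), 0)
  expect_true(all(diff(inh) > 0))
  ind <- vapply(c(0, 150, 600), function(d) auc_with("rifampin", d), 0)
  expect_true(all(diff(ind) < 0))
})

test_that("shared-enzyme trajectories respond to a time-dependent inactivator", {
  ipa <- ipatasertib_final()
  sim <- simulate_subject(ipa, dose_regimen("ipatasertib", 600, "oral", 24, 8),
                          t_end = 216, opts = quick_opts)
  expect_lt(min(sim$enzyme[, "E_liver"]), 0.9)   # inactivation happened
  expect_true(all(sim$enzyme > 0))
  # without TDI the pools stay at baseline
  sim0 <- simulate_subject(without_tdi(ipa),
                           dose_regimen("ipatasertib", 600, "oral", 24, 8),
                           t_end = 216, opts = quick_opts)
  expect_equal(max(abs(sim0$enzyme - 1)), 0, tolerance = 1e-8)
})

test_that("paired trials are seed-reproducible and respect a null perpetrator", {
  ipa <- ipatasertib_final()
  cfg <- scenario_config(
    name = "null-perpetrator",
    victim = list(record = ipa,
                  regimen = dose_regimen("ipatasertib", 100, "oral")),
    perpetrator = list(record = perpetrator_fixture("itraconazole"),
                       regimen = dose_regimen("itraconazole", 0, "oral")),
    n_trials = 1, n_subjects = 3, seed = 5, t_end = 96,
    metric = "auc_0_inf", window_start = 0)
  rep0 <- run_scenario(cfg, opts = quick_opts)
  expect_equal(rep0$per_subject$auc_combo, rep0$per_subject$auc_alone)
  expect_equal(rep0$gmr_auc$geo_mean_ratio, 1)
  rep1 <- run_scenario(cfg, opts = quick_opts)
  expect_identical(rep0$gmr_auc, rep1$gmr_auc)
})
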