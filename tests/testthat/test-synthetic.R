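test_that("noise-free synthetic observations equal the engine output", {
  rec <- linear_probe()
  reg <- dose_regimen("probe", 50, "oral")
  st <- generate_profiles(rec, reg, residual_cv = 0, n = 2, seed = 3,
                          cv_map = no_variability(), opts = quick_opts)
  sim <- simulate_subject(rec, reg, t_end = 73, opts = quick_opts)
  ref <- approx(sim$time, sim$plasma[, 1], xout = st$design$sampling_times)$y
  for (s in 1:2) {
    obs <- st$observations[st$observations$subject == s, ]
    expect_equal(obs$conc_ng_per_ml, ref, tolerance = 1e-12)
  }
})

test_that("synthetic datasets are seed-reproducible", {
  rec <- linear_probe()
  reg <- dose_regimen("probe", 50, "oral")
  a <- generate_profiles(rec, reg, residual_cv = 0.2, n = 4, seed = 9,
                         opts = quick_opts)
  b <- generate_profiles(rec, reg, residual_cv = 0.2, n = 4, seed = 9,
                         opts = quick_opts)
  expect_identical(a$observations, b$observations)
  c <- generate_profiles(rec, reg, residual_cv = 0.2, n = 4, seed = 10,
                         opts = quick_opts)
  expect_false(identical(a$observations, c$observations))
})

test_that("the realized residual CV matches the requested one", {
  rec <- linear_probe()
  reg <- dose_regimen("probe", 50, "oral")
  st <- generate_profiles(rec, reg, residual_cv = 0.2, n = 200, seed = 21,
                          cv_map = no_variability(), opts = quick_opts)
  sim <- simulate_subject(rec, reg, t_end = 73, opts = quick_opts)
  ref <- approx(sim$time, sim$plasma[, 1], xout = st$design$sampling_times)$y
  resid <- st$observations$conc_ng_per_ml / rep(ref, times = 200)
  cv <- sqrt(exp(stats::var(log(resid))) - 1)
  expect_gt(cv, 0.18); expect_lt(cv, 0.22)
})

test_that("a linear truth yields dose-independent synthetic CL/F", {
  rec <- linear_limit_ipa()
  st <- generate_dose_escalation(rec, doses = c(25, 100, 400),
                                 opts = solver_options(dt_out = 1))
  byphase <- split(st$observations, st$observations$phase)
  for (ph in byphase)
    expect_lt(diff(range(ph$cl_over_f)) / mean(ph$cl_over_f), 0.02)
})

test_that("DDI anchors are deterministic without jitter and propagate zero dose", {
  rec <- without_tdi(ipatasertib_final())
  a <- generate_ddi_anchor(rec, "itraconazole_100mg")
  b <- generate_ddi_anchor(rec, "itraconazole_100mg")
  expect_identical(a, b)
  expect_gt(a, 1)  # a strong inhibitor must raise exposure
  set.seed(1)
  j1 <- generate_ddi_anchor(rec, "itraconazole_100mg", jitter_cv = 0.1,
                            seed = 4)
  j2 <- generate_ddi_anchor(rec, "itraconazole_100mg", jitter_cv = 0.1,
                            seed = 4)
  expect_identical(j1, j2)
  expect_false(identical(a, j1))
})

test_that("synthetic exports carry a truth manifest", {
  rec <- linear_probe()
  st <- generate_profiles(rec, dose_regimen("probe", 50, "oral"),
                          residual_cv = 0, n = 1, seed = 2,
                          cv_map = no_variability(), opts = quick_opts)
  f <- tempfile(fileext = ".csv")
  export_synthetic_csv(st, f)
  expect_true(file.exists(f))
  man <- jsonlite::read_json(paste0(f, ".truth.json"))
  expect_equal(man$name, "probe")
  expect_equal(man$cl_additional, 100)
})
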