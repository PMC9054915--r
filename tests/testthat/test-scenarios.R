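test_that("a small itraconazole trial shows spread around a central GMR", {
  cfg <- scenario_itz_calibration(n_trials = 2, n_subjects = 3, seed = 17)
  rep <- run_scenario(cfg, opts = quick_opts)
  rs <- rep$per_subject$auc_combo / rep$per_subject$auc_alone
  expect_gt(stats::sd(log(rs)), 0)               # between-subject spread
  expect_gt(rep$gmr_auc$geo_mean_ratio, min(rs) - 1e-12)
  expect_lt(rep$gmr_auc$geo_mean_ratio, max(rs) + 1e-12)
  expect_lte(rep$gmr_auc$ci_low, rep$gmr_auc$geo_mean_ratio)
  expect_gte(rep$gmr_auc$ci_high, rep$gmr_auc$geo_mean_ratio)
  expect_gt(rep$gmr_auc$geo_mean_ratio, 1)       # inhibitor raises exposure
})

test_that("trial exports write tidy CSV plus a manifest", {
  cfg <- scenario_itz_calibration(n_trials = 1, n_subjects = 2, seed = 31)
  tr <- simulate_trial(cfg, opts = quick_opts)
  f <- tempfile(fileext = ".csv")
  export_trial_csv(tr, f)
  df <- utils::read.csv(f)
  expect_setequal(unique(df$arm), c("alone", "combo"))
  expect_true(all(c("subject", "compound", "time_h", "conc_ng_per_ml")
                  %in% names(df)))
  man <- jsonlite::read_json(paste0(f, ".manifest.json"))
  expect_equal(man$seed, 31)
})

test_that("fixture qualification passes the shipped records and fails corrupted ones", {
  q_itz <- qualify_fixture("itraconazole", opts = quick_opts)
  expect_true(q_itz$pass)
  q_mdz <- qualify_fixture("midazolam", opts = quick_opts)
  expect_true(q_mdz$pass)
  # negative control: a thousand-fold weaker Ki must fail the strong-class
  # envelope
  bad <- perpetrator_fixture("itraconazole")
  bad$interaction$ki <- bad$interaction$ki * 1000
  q_bad <- qualify_fixture("itraconazole", record = bad, opts = quick_opts)
  expect_false(q_bad$pass)
  expect_error(qualify_fixture("ipatasertib", record = ipatasertib_final()),
               "no qualification rules")
})

test_that("moderate and weak inhibitor and inducer fixtures sit in their class envelopes", {
  for (nm in c("erythromycin", "diltiazem", "fluvoxamine", "rifampin",
               "efavirenz")) {
    q <- qualify_fixture(nm, opts = quick_opts)
    expect_true(q$pass, label = paste(nm, "qualification"))
  }
})

test_that("scenario configs validate their structure", {
  expect_error(scenario_application("warfarin"), "no registered")
  cfg <- scenario_application("diltiazem", n_trials = 2, n_subjects = 2)
  expect_s3_class(cfg, "scenario_config")
  expect_equal(cfg$perpetrator$regimen$interval, 12)
  expect_equal(cfg$perpetrator$regimen$n_doses, 42)
  expect_equal(cfg$t_end, 504)
})
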