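test_that("molar/mass conversions round-trip exactly", {
  mws <- c(458, 325.8, 705.6, 822.9)
  x <- c(0.195, 9.66, 4.4, 123.4)
  expect_equal(ngml_to_um(um_to_ngml(x, mws), mws), x, tolerance = 1e-12)
  expect_equal(um_to_ngml(ngml_to_um(x, mws), mws), x, tolerance = 1e-12)
  # ipatasertib Km on the mass scale
  expect_equal(um_to_ngml(0.195, 458), 89.31, tolerance = 1e-3)
})

test_that("the final ipatasertib record carries the published parameter set", {
  ipa <- ipatasertib_final()
  expect_silent(validate_compound(ipa))
  expect_equal(ipa$mw, 458)
  expect_equal(ipa$compound_type, "diprotic_base")
  expect_equal(c(ipa$pka1, ipa$pka2), c(9, 4.9))
  expect_equal(ipa$bp_ratio, 1.43)
  expect_equal(ipa$fu_plasma, 0.63)
  expect_equal(c(ipa$fa, ipa$ka, ipa$fu_gut, ipa$q_gut), c(0.76, 0.76, 1, 9.28))
  expect_equal(ipa$vss_target, 39.13)
  expect_equal(ipa$cyp3a4$vmax, 0.135)
  expect_equal(ipa$cyp3a4$km, 0.195)
  expect_equal(c(ipa$cl_additional, ipa$cl_renal), c(2.7, 19.3))
  expect_equal(ipa$interaction$ki, 4.4)
  expect_equal(ipa$interaction$kapp, 9.66)
  expect_equal(ipa$interaction$kinact, 0.17)
})

test_that("perpetrator fixtures have the expected interaction structure", {
  itz <- perpetrator_fixture("itraconazole")
  expect_false(is.null(itz$interaction$ki))
  expect_null(itz$interaction$kinact)       # competitive only, no TDI
  rif <- perpetrator_fixture("rifampin")
  expect_false(is.null(rif$interaction$ind_max))
  expect_false(is.null(rif$interaction$ind_c50))
  ery <- perpetrator_fixture("erythromycin")
  expect_false(is.null(ery$interaction$kinact))
  # midazolam is predominantly CYP3A4-cleared at trace concentration
  expect_gt(fm_cyp3a4(perpetrator_fixture("midazolam"))$fm_total, 0.9)
  expect_error(perpetrator_fixture("warfarin"), "itraconazole")
})

test_that("compound records survive a text round trip", {
  ipa <- ipatasertib_final()
  f <- tempfile(fileext = ".txt")
  write_compound_file(ipa, f)
  back <- read_compound_file(f)
  expect_equal(back[names(back) != "peff"], ipa[names(ipa) != "peff"],
               tolerance = 1e-12)
  expect_equal(back$peff, ipa$peff)
})

test_that("record validation rejects out-of-range parameters by field", {
  ipa <- ipatasertib_final()
  bad <- ipa; bad$fu_plasma <- 1.2
  expect_error(validate_compound(bad), "fu_plasma")
  bad <- ipa; bad$cyp3a4$km <- 0
  expect_error(validate_compound(bad), "km")
  bad <- ipa; bad$interaction$ki <- -1
  expect_error(validate_compound(bad), "ki")
})

test_that("dose regimens validate their schedule", {
  reg <- dose_regimen("ipatasertib", 400, "oral", interval = 24, n_doses = 21)
  expect_equal(length(pbpkddi:::dose_times(reg)), 21)
  expect_equal(max(pbpkddi:::dose_times(reg)), 480)
  expect_error(dose_regimen("x", 10, "iv-infusion"), "duration")
  expect_error(dose_regimen("x", 10, "oral", interval = 0, n_doses = 2),
               "interval")
})

test_that("the Qgut utility blends villous flow and permeability clearance", {
  expect_equal(qgut_from_clperm(1e9, 18), 18, tolerance = 1e-6)
  expect_equal(qgut_from_clperm(18, 18), 9)
  expect_equal(qgut_from_clperm(0, 18), 0)
})
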