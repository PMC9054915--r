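test_that("a lipophobic neutral compound partitions like tissue water", {
  rec <- compound_record(name = "waterlike", mw = 100, logp = -10,
                         compound_type = "neutral", bp_ratio = 1,
                         fu_plasma = 1, fa = 1, ka = 1, q_gut = 10,
                         kp_scalar = 1)
  kp <- predict_kp_set(rec)
  comp <- pbpkddi:::.RR_COMP
  water <- comp$f_ew + comp$f_iw
  expect_equal(unname(kp[comp$tissue]), water, tolerance = 0.02)
})

test_that("the diprotic-base Kp pattern puts adipose below lean tissues", {
  kp <- predict_kp_set(ipatasertib_final())
  expect_true(all(kp > 0))
  expect_lt(kp[["adipose"]], kp[["muscle"]])
  expect_lt(kp[["adipose"]], kp[["liver"]])
})

test_that("strong-base Kp matches a hand-evaluated single-tissue oracle", {
  # independent re-evaluation of the muscle Kp from the raw composition
  # equations, outside the vectorized implementation
  rec <- ipatasertib_final()
  phys <- default_healthy_volunteer()
  hct <- phys$hematocrit
  fu <- rec$fu_plasma; p <- 10^rec$logp
  ion <- function(ph) 10^(rec$pka1 - ph) + 10^(rec$pka1 + rec$pka2 - 2 * ph)
  xp <- ion(7.4); xiw <- ion(7.0); xbc <- ion(7.22)
  kpu_bc <- (rec$bp_ratio - (1 - hct)) / (hct * fu)
  lip_rbc <- p * 0.0017 + (0.3 * p + 0.7) * 0.0029
  ka_ap <- (kpu_bc - (1 + xbc) / (1 + xp) * 0.603 - lip_rbc / (1 + xp)) *
    (1 + xp) / (0.5 * xbc)
  mus <- list(f_ew = 0.118, f_iw = 0.630, f_nl = 0.010, f_np = 0.0072,
              ap = 1.53)
  kpu <- mus$f_ew + (1 + xiw) / (1 + xp) * mus$f_iw +
    ka_ap * mus$ap * xiw / (1 + xp) +
    (p * mus$f_nl + (0.3 * p + 0.7) * mus$f_np) / (1 + xp)
  expect_equal(predict_kp_set(rec)[["muscle"]], kpu * fu, tolerance = 1e-10)
})

test_that("Kp prediction demands the physicochemistry it uses", {
  rec <- ipatasertib_final()
  rec$logp <- NA_real_
  expect_error(predict_kp_set(rec), "logp")
  rec2 <- ipatasertib_final()
  rec2$pka1 <- NA_real_
  expect_error(validate_compound(rec2), "pka1")
})

test_that("Vss reduces to total volume over body weight in the unit case", {
  phys <- default_healthy_volunteer()
  rec <- ipatasertib_final()
  rec$bp_ratio <- 1
  kps <- setNames(rep(1, 11), pbpkddi:::.TISSUES)
  vols <- phys$tissue_volumes
  expect_equal(compute_vss(kps, phys, rec, scalar = 1),
               sum(vols) / phys$body_weight, tolerance = 1e-12)
})

test_that("Vss equals an independent brute-force sum and grows with the scalar", {
  phys <- default_healthy_volunteer()
  rec <- ipatasertib_final()
  kps <- predict_kp_set(rec, phys)
  for (s in c(0.5, 1, 4.47)) {
    acc <- (1 - phys$hematocrit) *
      (phys$tissue_volumes[["arterial_blood"]] +
         phys$tissue_volumes[["venous_blood"]])
    for (t in names(kps)) acc <- acc + s * kps[[t]] * phys$tissue_volumes[[t]]
    acc <- acc + phys$hematocrit *
      (phys$tissue_volumes[["arterial_blood"]] +
         phys$tissue_volumes[["venous_blood"]]) *
      (rec$bp_ratio - (1 - phys$hematocrit)) / phys$hematocrit
    expect_equal(compute_vss(kps, phys, rec, s), acc / phys$body_weight,
                 tolerance = 1e-12)
  }
  v <- vapply(c(1, 2, 4, 8), function(s) compute_vss(kps, phys, rec, s), 0)
  expect_true(all(diff(v) > 0))
})

test_that("the Kp scalar root find is a fixed point and round-trips to 1e-6", {
  phys <- default_healthy_volunteer()
  rec <- ipatasertib_final()
  kps <- predict_kp_set(rec, phys)
  v1 <- compute_vss(kps, phys, rec, scalar = 1)
  expect_equal(find_kp_scalar(rec, phys, target_vss = v1, kps = kps), 1,
               tolerance = 1e-6)
  s <- find_kp_scalar(rec, phys, target_vss = 39.13, kps = kps)
  expect_equal(compute_vss(kps, phys, rec, s), 39.13, tolerance = 1e-6)
  expect_error(find_kp_scalar(rec, phys, target_vss = 1e-6, kps = kps),
               "floor")
})
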