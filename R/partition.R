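# Mechanistic tissue:plasma partition coefficients (Rodgers-Rowland style).
#
# Moderate-to-strong bases (pKa of the most basic centre >= 7) partition into
# tissue water, neutral lipid, neutral phospholipid and - for the ionized
# species - acidic phospholipid, with the acidic-phospholipid association
# constant back-calculated from the blood:plasma ratio. Weak bases, acids and
# neutrals use the extracellular-protein (albumin-ratio) form instead.
# Adipose neutral-lipid partitioning uses the vegetable-oil:water surrogate
# applied to logD at plasma pH, as is conventional.

# tissue composition: fractional water (extra/intracellular), neutral lipid,
# neutral phospholipid, acidic phospholipid (mg/g), albumin ratio
.RR_COMP <- data.frame(
  tissue = c("lung", "adipose", "bone", "brain", "gut", "heart", "kidney",
             "liver", "muscle", "skin", "spleen"),
  f_ew = c(0.336, 0.135, 0.100, 0.162, 0.282, 0.320, 0.273, 0.161, 0.118,
           0.382, 0.207),
  f_iw = c(0.446, 0.017, 0.346, 0.620, 0.475, 0.456, 0.483, 0.573, 0.630,
           0.291, 0.579),
  f_nl = c(0.022, 0.853, 0.017, 0.039, 0.038, 0.014, 0.012, 0.014, 0.010,
           0.060, 0.0077),
  f_np = c(0.0128, 0.0016, 0.0017, 0.0015, 0.0125, 0.0111, 0.0242, 0.024,
           0.0072, 0.0044, 0.0113),
  ap   = c(3.91, 0.40, 0.67, 0.40, 2.41, 2.25, 5.03, 4.56, 1.53, 1.32, 3.18),
  ra   = c(0.212, 0.049, 0.100, 0.048, 0.158, 0.157, 0.130, 0.086, 0.064,
           0.277, 0.097),
  stringsAsFactors = FALSE
)
.RR_RBC <- list(f_iw = 0.603, f_nl = 0.0017, f_np = 0.0029, ap = 0.50,
                ph = 7.22)
.RR_PH_PLASMA <- 7.4
.RR_PH_IW <- 7.0
.RR_PLASMA_NL <- 0.0023
.RR_PLASMA_NP <- 0.0013

# sum of ionization terms for the water phase at a given pH
.ionization <- function(rec, ph) {
  switch(rec$compound_type,
    neutral = 0,
    acid = 10^(ph - rec$pka1),
    monoprotic_base = 10^(rec$pka1 - ph),
    diprotic_base = 10^(rec$pka1 - ph) + 10^(rec$pka1 + rec$pka2 - 2 * ph)
  )
}

.is_strong_base <- function(rec) {
  rec$compound_type %in% c("monoprotic_base", "diprotic_base") &&
    is.finite(rec$pka1) && rec$pka1 >= 7
}

# vegetable-oil:water distribution surrogate for the adipose neutral-lipid
# phase, from logD at plasma pH
.d_vow <- function(rec) {
  logd <- rec$logp - log10(1 + .ionization(rec, .RR_PH_PLASMA))
  10^(1.115 * logd - 1.35)
}

#' Predict tissue:plasma partition coefficients
#'
#' Mechanistic (tissue-composition based) Kp prediction for all perfused
#' non-blood tissues, from logP, ionization class, blood:plasma ratio and
#' plasma protein binding. Strong bases bind acidic phospholipids with an
#' association constant back-calculated from the erythrocyte partition
#' implied by the blood:plasma ratio; weak bases, acids and neutrals use
#' tissue:plasma protein-binding ratios.
#'
#' @param rec a `compound_record` (needs `logp`, `compound_type`, pKa(s),
#'   `bp_ratio`, `fu_plasma`).
#' @param phys a `system_physiology` (hematocrit).
#' @return named numeric vector of Kp (total tissue:total plasma), one per
#'   non-blood tissue; all positive.
#' @export
#' @examples
#' predict_kp_set(ipatasertib_final())
predict_kp_set <- function(rec, phys = default_healthy_volunteer()) {
  validate_compound(rec)
  for (f in c("logp", "bp_ratio", "fu_plasma"))
    if (!is.finite(rec[[f]])) stop("missing physicochemistry field: ", f)
  if (rec$compound_type != "neutral" && !is.finite(rec$pka1))
    stop("missing physicochemistry field: pka1")
  hct <- phys$hematocrit
  fu <- rec$fu_plasma
  p <- 10^rec$logp
  x_p <- .ionization(rec, .RR_PH_PLASMA)
  x_iw <- .ionization(rec, .RR_PH_IW)
  lip <- function(f_nl, f_np, p_nl = p) p_nl * f_nl + (0.3 * p + 0.7) * f_np

  comp <- .RR_COMP
  if (.is_strong_base(rec)) {
    # KaAP from the erythrocyte partition implied by B/P
    kpu_bc <- (rec$bp_ratio - (1 - hct)) / (hct * fu)
    if (kpu_bc <= 0)
      stop("blood:plasma ratio inconsistent with hematocrit for ", rec$name)
    x_bc <- .ionization(rec, .RR_RBC$ph)
    ka_ap <- (kpu_bc -
                (1 + x_bc) / (1 + x_p) * .RR_RBC$f_iw -
                lip(.RR_RBC$f_nl, .RR_RBC$f_np) / (1 + x_p)) *
      (1 + x_p) / (.RR_RBC$ap * x_bc)
    ka_ap <- max(ka_ap, 0)
    kpu <- comp$f_ew +
      (1 + x_iw) / (1 + x_p) * comp$f_iw +
      ka_ap * comp$ap * x_iw / (1 + x_p) +
      ifelse(comp$tissue == "adipose",
             lip(comp$f_nl, comp$f_np, .d_vow(rec)),
             lip(comp$f_nl, comp$f_np)) / (1 + x_p)
  } else {
    plasma_lip <- lip(.RR_PLASMA_NL, .RR_PLASMA_NP)
    prot <- pmax(1 / fu - 1 - plasma_lip, 0)
    kpu <- comp$f_ew +
      (1 + x_iw) / (1 + x_p) * comp$f_iw +
      ifelse(comp$tissue == "adipose",
             lip(comp$f_nl, comp$f_np, .d_vow(rec)),
             lip(comp$f_nl, comp$f_np)) / (1 + x_p) +
      comp$ra * prot
  }
  kp <- kpu * fu
  if (any(!is.finite(kp)) || any(kp <= 0))
    stop("non-positive Kp predicted for ", rec$name)
  setNames(kp, comp$tissue)
}

#' Steady-state volume of distribution from a Kp set
#'
#' `Vss = (V_plasma + sum_t scalar * Kp_t * V_t + V_ery * K_ery) / BW`, with
#' the erythrocyte partition `K_ery = (B/P - (1 - Hct)) / Hct` implied by the
#' blood:plasma ratio.
#'
#' @param kps named Kp vector as from [predict_kp_set()].
#' @param phys a `system_physiology`.
#' @param rec a `compound_record` (for B/P).
#' @param scalar uniform Kp multiplier (> 0).
#' @return Vss in L/kg.
#' @export
compute_vss <- function(kps, phys, rec, scalar = 1) {
  stopifnot(scalar > 0)
  vols <- phys$tissue_volumes
  v_blood <- vols[["arterial_blood"]] + vols[["venous_blood"]]
  hct <- phys$hematocrit
  v_plasma <- (1 - hct) * v_blood
  v_ery <- hct * v_blood
  k_ery <- (rec$bp_ratio - (1 - hct)) / hct
  tiss <- names(kps)
  total <- v_plasma + sum(scalar * kps * vols[tiss]) + v_ery * k_ery
  unname(total / phys$body_weight)
}

#' Resolve the Kp scalar matching an observed Vss
#'
#' Monotone one-dimensional root find: Vss is strictly increasing in the
#' scalar, so bisection on the bracketed log-scalar converges to the target
#' within 1e-6 relative.
#'
#' @param rec a `compound_record` with `vss_target` or an explicit target.
#' @param phys a `system_physiology`.
#' @param target_vss observed Vss (L/kg); defaults to `rec$vss_target`.
#' @param kps optional precomputed Kp set.
#' @return the scalar (unitless).
#' @export
find_kp_scalar <- function(rec, phys = default_healthy_volunteer(),
                           target_vss = rec$vss_target, kps = NULL) {
  if (!is.finite(target_vss)) stop("no Vss target available for ", rec$name)
  if (is.null(kps)) kps <- predict_kp_set(rec, phys)
  floor_vss <- compute_vss(kps, phys, rec, scalar = 1e-9)
  if (target_vss <= floor_vss)
    stop("target Vss below the blood-volume floor (", signif(floor_vss, 3),
         " L/kg)")
  f <- function(ls) compute_vss(kps, phys, rec, exp(ls)) - target_vss
  lo <- log(1e-6); hi <- log(1e6)
  if (f(hi) < 0) stop("target Vss unreachable with scalar <= 1e6")
  r <- uniroot(f, c(lo, hi), tol = 1e-12)
  scalar <- exp(r$root)
  got <- compute_vss(kps, phys, rec, scalar)
  if (abs(got - target_vss) / target_vss > 1e-6)
    stop("Kp scalar root find did not converge")
  scalar
}

#' Scaled Kp set used by the simulation engine
#'
#' Returns `scalar * Kp` per tissue. When the record carries an observed
#' `vss_target` the scalar is resolved with [find_kp_scalar()] so the model
#' reproduces the observed steady-state volume exactly (the scalar absorbs
#' any difference between this Kp prediction and the one the target was
#' derived with); otherwise the record's nominal `kp_scalar` is applied.
#'
#' @param rec a `compound_record`.
#' @param phys a `system_physiology`.
#' @return named vector of scaled partition coefficients.
#' @export
scaled_kp_set <- function(rec, phys = default_healthy_volunteer()) {
  kps <- predict_kp_set(rec, phys)
  scalar <- if (is.finite(rec$vss_target))
    find_kp_scalar(rec, phys, rec$vss_target, kps) else rec$kp_scalar
  kps * scalar
}
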