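#' Non-compartmental analysis of a single concentration-time profile
#'
#' Linear-up/log-down trapezoidal AUC; terminal slope from log-linear
#' regression over the terminal run of at least three post-peak points that
#' maximizes adjusted R-squared (ties broken toward fewer points);
#' `AUC0-inf = AUC0-t + Clast / lambda_z`; `CL/F = dose / AUC0-inf`.
#'
#' @param time sampling times (h), increasing.
#' @param conc concentrations (ng/mL).
#' @param dose administered dose (mg); `NA` suppresses CL/F.
#' @param tau dosing interval (h) over which to report `auc_tau` (from
#'   `time[1]`), or `NULL`.
#' @return object of class `pk_summary`: list with `auc_0_t`, `auc_0_inf`,
#'   `auc_tau`, `cmax`, `tmax`, `lambda_z`, `cl_over_f`,
#'   `extrapolated_fraction` (units: ng*h/mL, ng/mL, h, 1/h, L/h). Fields
#'   depending on a non-estimable terminal slope are `NA`.
#' @export
#' @examples
#' t <- seq(0, 48, 0.5); c0 <- 100 * exp(-0.1 * t)
#' nca_single(t, c0, dose = 1)$lambda_z
nca_single <- function(time, conc, dose = NA, tau = NULL) {
  stopifnot(length(time) == length(conc), !is.unsorted(time))
  keep <- is.finite(time) & is.finite(conc)
  time <- time[keep]; conc <- pmax(conc[keep], 0)
  if (sum(conc > 0) < 3) stop("need at least 3 positive concentrations")

  auc_0_t <- .auc_linuplogdown(time, conc)
  imax <- which.max(conc)
  cmax <- conc[imax]; tmax <- time[imax]

  lz <- .lambda_z(time, conc, imax)
  clast <- conc[max(which(conc > 0))]
  if (is.na(lz$lambda)) {
    auc_inf <- NA_real_; clf <- NA_real_; extra <- NA_real_
  } else {
    auc_inf <- auc_0_t + clast / lz$lambda
    extra <- (clast / lz$lambda) / auc_inf
    clf <- if (is.finite(dose)) dose * 1e6 / auc_inf / 1000 else NA_real_
    # dose mg -> ng; AUC ng*h/mL -> CL in mL/h -> /1000 to L/h
  }
  auc_tau <- if (!is.null(tau)) {
    win <- time <= time[1] + tau + 1e-9
    .auc_linuplogdown(time[win], conc[win])
  } else NA_real_

  structure(list(auc_0_t = auc_0_t, auc_0_inf = auc_inf, auc_tau = auc_tau,
                 cmax = cmax, tmax = tmax, lambda_z = lz$lambda,
                 n_lambda = lz$n, cl_over_f = clf,
                 extrapolated_fraction = extra),
            class = "pk_summary")
}

# linear interpolation up, log-trapezoid down (standard NCA rule)
.auc_linuplogdown <- function(time, conc) {
  dt <- diff(time); c1 <- conc[-length(conc)]; c2 <- conc[-1]
  seg <- ifelse(c2 >= c1 | c1 <= 0 | c2 <= 0,
                (c1 + c2) / 2 * dt,
                (c1 - c2) / log(c1 / c2) * dt)
  sum(seg)
}

.lambda_z <- function(time, conc, imax) {
  pos <- which(conc > 0 & seq_along(conc) > imax)
  if (length(pos) < 3) return(list(lambda = NA_real_, n = 0L))
  best <- NULL
  for (k in 3:length(pos)) {
    idx <- pos[(length(pos) - k + 1):length(pos)]
    tt <- time[idx]; ly <- log(conc[idx])
    if (length(unique(tt)) < 3) next
    mt <- mean(tt); my <- mean(ly)
    sxx <- sum((tt - mt)^2); sxy <- sum((tt - mt) * (ly - my))
    syy <- sum((ly - my)^2)
    sl <- -sxy / sxx
    if (!is.finite(sl) || sl <= 0) next
    r2 <- if (syy > 0) sxy^2 / (sxx * syy) else 1
    adj <- 1 - (1 - r2) * (k - 1) / (k - 2)
    if (is.null(best) || adj > best$r2 + 1e-12)
      best <- list(lambda = sl, n = k, r2 = adj)
  }
  if (is.null(best)) list(lambda = NA_real_, n = 0L) else best
}

#' Renal clearance from urinary recovery
#'
#' `CL_R = Ae / AUC0-inf`, the amount of unchanged drug excreted in urine
#' over the area under the plasma curve.
#'
#' @param ae amount excreted unchanged in urine (mg).
#' @param auc_0_inf plasma AUC extrapolated to infinity (mg*h/L).
#' @return renal clearance (L/h).
#' @export
#' @examples
#' renal_clearance(10, 2) # 5 L/h
renal_clearance <- function(ae, auc_0_inf) {
  stopifnot(ae >= 0, auc_0_inf > 0)
  ae / auc_0_inf
}

#' Paired geometric mean ratio with 90% confidence interval
#'
#' Ratio of geometric means of paired per-subject metrics; the confidence
#' interval comes from the t-distribution on the within-subject log
#' differences, the standard crossover/DDI analysis.
#'
#' @param metric_with per-subject values in the presence of the perpetrator.
#' @param metric_without paired values without the perpetrator.
#' @param level confidence level (default 0.90).
#' @return object of class `gmr_result`: `geo_mean_ratio`, `ci_low`,
#'   `ci_high`, `n`.
#' @export
#' @examples
#' paired_gmr(c(2, 4, 8), c(1, 2, 4))
paired_gmr <- function(metric_with, metric_without, level = 0.90) {
  stopifnot(length(metric_with) == length(metric_without))
  bad <- which(!(metric_with > 0) | !(metric_without > 0))
  if (length(bad))
    stop("nonpositive metric for subject index ", paste(bad, collapse = ", "))
  d <- log(metric_with) - log(metric_without)
  n <- length(d)
  m <- mean(d)
  half <- if (n > 1 && sd(d) > 0) qt(1 - (1 - level) / 2, n - 1) * sd(d) / sqrt(n) else 0
  structure(list(geo_mean_ratio = exp(m), ci_low = exp(m - half),
                 ci_high = exp(m + half), n = n),
            class = "gmr_result")
}

#' @export
print.gmr_result <- function(x, ...) {
  cat(sprintf("GMR %.3f (90%% CI %.3f-%.3f), n = %d\n", x$geo_mean_ratio,
              x$ci_low, x$ci_high, x$n))
  invisible(x)
}

#' Geometric mean and geometric CV% of a positive sample
#'
#' @param x positive numeric vector.
#' @return list with `geo_mean` and `geo_cv_pct`
#'   (`100 * sqrt(exp(var(log x)) - 1)`).
#' @export
geo_summary <- function(x) {
  stopifnot(all(x > 0))
  lx <- log(x)
  list(geo_mean = exp(mean(lx)),
       geo_cv_pct = if (length(x) > 1) 100 * sqrt(exp(stats::var(lx)) - 1) else 0)
}
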