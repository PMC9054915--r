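#' Virtual healthy-volunteer system physiology
#'
#' The system (drug-independent) side of the PBPK model: organ volumes and
#' blood flows of a 70-kg reference adult, hepatic and gut CYP3A4 abundance,
#' and enzyme turnover rates. Values are loaded from the versioned plain-text
#' fixture shipped in `inst/extdata/physiology/` so they can be audited and
#' edited in one place.
#'
#' The flow convention follows whole-body PBPK practice: `tissue_blood_flows`
#' holds the *inflow* of each systemic tissue, with `liver` being the hepatic
#' artery only; gut and spleen venous outflow drains through the liver. The
#' systemic inflows sum exactly to cardiac output.
#'
#' @param file optional path to an alternative physiology fixture file.
#' @return an object of class `system_physiology`: a list with fields
#'   `body_weight` (kg), `tissue_volumes` (named, L; includes
#'   `arterial_blood`/`venous_blood`), `tissue_blood_flows` (named, L/h),
#'   `cardiac_output` (L/h), `hematocrit`, `liver_weight` (g), `mppgl`
#'   (mg microsomal protein/g liver), `cyp3a4_hepatic_abundance` (pmol/mg),
#'   `cyp3a4_gut_total` (nmol), `kdeg_hepatic` and `kdeg_gut` (1/h), and
#'   `q_villi` (L/h).
#' @export
#' @examples
#' phys <- default_healthy_volunteer()
#' sum(phys$tissue_blood_flows) - phys$cardiac_output
default_healthy_volunteer <- function(file = NULL) {
  if (is.null(file)) {
    if (!is.null(.pkg_cache$phys)) return(.pkg_cache$phys)
    file <- .extdata("physiology", "healthy_volunteer.txt")
    cache <- TRUE
  } else cache <- FALSE
  kv <- .read_kv_file(file)
  pick <- function(key) {
    v <- kv[[key]]
    if (is.null(v)) stop("physiology fixture missing key: ", key, call. = FALSE)
    v
  }
  vols <- vapply(c(.TISSUES, "arterial_blood", "venous_blood"),
                 function(t) pick(paste0("tissue_volume.", t)), 0)
  flows <- vapply(.SYSTEMIC,
                  function(t) pick(paste0("tissue_blood_flow.", t)), 0)
  phys <- structure(list(
    body_weight = pick("body_weight"),
    tissue_volumes = vols,
    tissue_blood_flows = flows,
    cardiac_output = pick("cardiac_output"),
    hematocrit = pick("hematocrit"),
    liver_weight = pick("liver_weight"),
    mppgl = pick("mppgl"),
    cyp3a4_hepatic_abundance = pick("cyp3a4_hepatic_abundance"),
    cyp3a4_gut_total = pick("cyp3a4_gut_total"),
    kdeg_hepatic = pick("kdeg_hepatic"),
    kdeg_gut = pick("kdeg_gut"),
    q_villi = pick("q_villi")
  ), class = "system_physiology")
  validate_physiology(phys)
  if (cache) .pkg_cache$phys <- phys
  phys
}

.read_kv_file <- function(file) {
  lines <- readLines(file, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  out <- list()
  for (ln in lines) {
    parts <- strsplit(ln, "[[:space:]]+")[[1]]
    if (length(parts) < 2) stop("malformed fixture line: ", ln, call. = FALSE)
    key <- parts[1]
    val <- suppressWarnings(as.numeric(parts[2]))
    out[[key]] <- if (is.na(val)) parts[2] else val
  }
  out
}

#' Validate a system physiology record
#'
#' Checks the structural invariants: strictly positive volumes and flows, a
#' flow balance (systemic inflows sum to cardiac output to 1e-9 relative),
#' hematocrit a fraction, and hepatic total CYP3A4 exceeding the gut total.
#'
#' @param phys a `system_physiology` object.
#' @return `phys`, invisibly; stops on violation.
#' @export
validate_physiology <- function(phys) {
  stopifnot(inherits(phys, "system_physiology"))
  if (any(phys$tissue_volumes <= 0)) stop("non-positive tissue volume")
  if (any(phys$tissue_blood_flows <= 0)) stop("non-positive tissue blood flow")
  if (phys$cardiac_output <= 0) stop("non-positive cardiac output")
  rel <- abs(sum(phys$tissue_blood_flows) - phys$cardiac_output) /
    phys$cardiac_output
  if (rel > 1e-9)
    stop("tissue blood flows do not balance cardiac output (rel err ",
         format(rel), ")")
  if (phys$hematocrit <= 0 || phys$hematocrit >= 1) stop("hematocrit not a fraction")
  hep_total <- phys$cyp3a4_hepatic_abundance * phys$mppgl * phys$liver_weight
  if (hep_total <= phys$cyp3a4_gut_total * 1000)
    stop("hepatic CYP3A4 total must exceed gut total")
  invisible(phys)
}

#' Total hepatic CYP3A4 content
#'
#' @param phys a `system_physiology` object.
#' @return hepatic CYP3A4 content in pmol (abundance x MPPGL x liver weight).
#' @export
hepatic_cyp3a4_total <- function(phys) {
  phys$cyp3a4_hepatic_abundance * phys$mppgl * phys$liver_weight
}

#' Between-subject variability specification
#'
#' Lognormal coefficients of variation applied multiplicatively (median
#' preserved) to selected system or drug parameters when sampling a virtual
#' population. Recognized names: `cyp3a4_hepatic_abundance`,
#' `cyp3a4_gut_total` (system side) and `fa`, `ka`, `cl_renal`,
#' `cl_additional` (victim-compound side, carried as per-subject multipliers).
#'
#' @param cv_map named numeric vector of lognormal CVs (fractions in `[0, 2]`).
#' @param seed integer seed controlling the population draw.
#' @return an object of class `variability_spec`.
#' @export
#' @examples
#' variability_spec(c(cyp3a4_hepatic_abundance = 0.45, fa = 0.3), seed = 1)
variability_spec <- function(cv_map = default_cv_map(), seed = 1L) {
  stopifnot(is.numeric(cv_map))
  if (is.null(names(cv_map)) || any(!nzchar(names(cv_map))))
    stop("cv_map must be fully named")
  bad <- names(cv_map)[cv_map < 0 | cv_map > 2 | !is.finite(cv_map)]
  if (length(bad))
    stop("invalid CV for parameter(s): ", paste(bad, collapse = ", "))
  known <- c("cyp3a4_hepatic_abundance", "cyp3a4_gut_total",
             "fa", "ka", "cl_renal", "cl_additional")
  unk <- setdiff(names(cv_map), known)
  if (length(unk))
    stop("unknown variability parameter(s): ", paste(unk, collapse = ", "))
  structure(list(cv_map = cv_map, seed = as.integer(seed)),
            class = "variability_spec")
}

#' Default between-subject CVs
#'
#' Dominant PK variability sources for a CYP3A4-cleared drug: enzyme
#' abundances and the victim's absorption and non-CYP clearance terms.
#'
#' @return named numeric vector of lognormal CVs.
#' @export
default_cv_map <- function() {
  c(cyp3a4_hepatic_abundance = 0.45,
    cyp3a4_gut_total = 0.45,
    fa = 0.3,
    ka = 0.3,
    cl_renal = 0.3,
    cl_additional = 0.3)
}

#' Sample a virtual population
#'
#' Draws `n` subjects around a base physiology. Each parameter named in the
#' variability spec is drawn lognormally with median equal to the base value
#' and the requested CV (`sdlog = sqrt(log(1 + CV^2))`); everything else is
#' copied. Compound-side parameters (`fa`, `ka`, `cl_renal`, `cl_additional`)
#' are returned as per-subject multipliers in the `"param_multipliers"`
#' attribute of each subject, applied to the victim record by
#' [simulate_trial()] (which caps the realized fa at 1; the cap does not move
#' the median while the base fa < 1).
#'
#' @param base a `system_physiology` object.
#' @param n number of subjects (>= 1).
#' @param spec a `variability_spec`.
#' @return list of `n` `system_physiology` objects.
#' @export
sample_population <- function(base, n, spec = variability_spec()) {
  validate_physiology(base)
  stopifnot(inherits(spec, "variability_spec"), n >= 1)
  n <- as.integer(n)
  cvs <- spec$cv_map
  sdlog <- sqrt(log(1 + cvs^2))
  set.seed(spec$seed)
  draws <- matrix(1, nrow = n, ncol = length(cvs),
                  dimnames = list(NULL, names(cvs)))
  for (j in seq_along(cvs)) {
    if (sdlog[j] > 0) draws[, j] <- exp(rnorm(n, 0, sdlog[j]))
  }
  sysnames <- intersect(colnames(draws),
                        c("cyp3a4_hepatic_abundance", "cyp3a4_gut_total"))
  cpdnames <- setdiff(colnames(draws), sysnames)
  lapply(seq_len(n), function(i) {
    subj <- base
    for (nm in sysnames) subj[[nm]] <- base[[nm]] * unname(draws[i, nm])
    attr(subj, "param_multipliers") <- draws[i, cpdnames, drop = TRUE]
    validate_physiology(subj)
    subj
  })
}

#' @export
print.system_physiology <- function(x, ...) {
  cat("<system_physiology> ", x$body_weight, " kg, CO ",
      x$cardiac_output, " L/h\n", sep = "")
  cat("  hepatic CYP3A4 total: ",
      format(hepatic_cyp3a4_total(x), big.mark = ","), " pmol; gut: ",
      x$cyp3a4_gut_total * 1000, " pmol\n", sep = "")
  invisible(x)
}
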