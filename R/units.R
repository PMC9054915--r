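#' Convert a molar concentration to a mass concentration
#'
#' PBPK enzyme kinetics are parameterized in micromolar units while plasma
#' concentrations are reported in ng/mL; with molecular weight in g/mol the
#' two scales are related by `ng/mL = uM * MW` (1 umol/L x 1 g/mol = 1 ug/L).
#'
#' @param um concentration in umol/L.
#' @param mw molecular weight in g/mol.
#' @return concentration in ng/mL.
#' @export
#' @examples
#' um_to_ngml(0.195, 458) # ipatasertib Km on the mass scale
um_to_ngml <- function(um, mw) {
  stopifnot(is.numeric(um), is.numeric(mw), all(mw > 0))
  um * mw
}

#' Convert a mass concentration to a molar concentration
#'
#' Inverse of [um_to_ngml()]; exact to machine precision both ways.
#'
#' @param ngml concentration in ng/mL.
#' @param mw molecular weight in g/mol.
#' @return concentration in umol/L.
#' @export
ngml_to_um <- function(ngml, mw) {
  stopifnot(is.numeric(ngml), is.numeric(mw), all(mw > 0))
  ngml / mw
}

#' Nominal gut flow from villous blood flow and a permeability clearance
#'
#' The hybrid "Qgut" of the gut first-pass model blends mucosal perfusion and
#' permeation: `Qgut = Qvilli * CLperm / (Qvilli + CLperm)`. Provided as a
#' utility; shipped compound records carry their Qgut directly.
#'
#' @param cl_perm permeability clearance across the enterocyte membrane (L/h).
#' @param q_villi villous mucosal blood flow (L/h).
#' @return nominal gut flow (L/h).
#' @export
qgut_from_clperm <- function(cl_perm, q_villi) {
  stopifnot(cl_perm >= 0, q_villi > 0)
  q_villi * cl_perm / (q_villi + cl_perm)
}
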