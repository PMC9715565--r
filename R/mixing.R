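# Endmember mixing reconstruction of the incubation starting solution and
# scalar extract chemistry arithmetic.

#' Iron-binding ligand excess
#'
#' `L' = L - dFe`. Negative results (more dissolved iron than ligand) are
#' returned as-is with a warning.
#'
#' @param L Ligand concentration (umol/L).
#' @param dfe Dissolved iron concentration (umol/L).
#' @return Ligand excess (umol/L), vectorised.
#' @export
#' @examples
#' ligand_excess(0.214, 0.071)  # 0.143
ligand_excess <- function(L, dfe) {
  out <- L - dfe
  if (any(out < 0, na.rm = TRUE))
    warning("negative ligand excess: dissolved Fe exceeds ligand concentration")
  out
}

#' Volume-weighted mixing of concentrations
#'
#' Concentration of a conservative tracer in the mixture of two endmember
#' waters: `(c_p v_p + c_c v_c) / (v_p + v_c)`.
#'
#' @param c_plume,c_control Endmember concentrations.
#' @param v_plume,v_control Mixed volumes (same unit).
#' @return Mixture concentration.
#' @export
#' @examples
#' mix_concentration(0.071, 0.2985, 50, 450)  # ~0.275
mix_concentration <- function(c_plume, c_control, v_plume, v_control) {
  stopifnot(v_plume + v_control > 0)
  (c_plume * v_plume + c_control * v_control) / (v_plume + v_control)
}

#' Carbon-weighted mixing of DOM characteristics
#'
#' Intensity-weighted DOM characteristics mix in proportion to the amount
#' of extractable carbon each endmember contributes: every characteristic is
#' averaged with weights `w = SPE-DOC x volume fraction`.
#'
#' @param summary_p,summary_c Named numeric vectors (or one-row data.frames)
#'   of endmember characteristics; shared numeric fields are mixed.
#' @param spe_doc_p,spe_doc_c Endmember SPE-DOC concentrations (umol/L).
#' @param v_plume,v_control Mixed volumes.
#' @return Named numeric vector of mixture characteristics.
#' @export
mix_dom_characteristics <- function(summary_p, summary_c, spe_doc_p,
                                    spe_doc_c, v_plume, v_control) {
  stopifnot(spe_doc_p > 0, spe_doc_c > 0)
  to_vec <- function(s) {
    if (is.data.frame(s)) s <- unlist(s[1, , drop = TRUE])
    s[!is.na(suppressWarnings(as.numeric(s)))]
  }
  p <- to_vec(summary_p); ctrl <- to_vec(summary_c)
  fields <- intersect(names(p), names(ctrl))
  vt <- v_plume + v_control
  w_p <- spe_doc_p * v_plume / vt
  w_c <- spe_doc_c * v_control / vt
  out <- (w_p * as.numeric(p[fields]) + w_c * as.numeric(ctrl[fields])) /
    (w_p + w_c)
  setNames(out, fields)
}

#' Mix formula intensity profiles
#'
#' Formula-wise weighted sum of two intensity profiles on the union of
#' their formulas (absent = 0). Feeding the result to [ideg()] gives the
#' degradation index of the mixture, e.g. with control weighted 9x against
#' the plume profile for a 50:450 starting solution.
#'
#' @param profile_p,profile_c Named numeric vectors (names = formulas).
#' @param weight_p,weight_c Profile weights (default 1 and 9).
#' @return Named numeric vector over the union of formulas.
#' @export
mix_intensity_profiles <- function(profile_p, profile_c, weight_p = 1,
                                   weight_c = 9) {
  formulas <- union(names(profile_p), names(profile_c))
  get0 <- function(x, f) ifelse(f %in% names(x), x[f], 0)
  out <- weight_p * get0(profile_p, formulas) + weight_c * get0(profile_c, formulas)
  setNames(as.numeric(out), formulas)
}

#' Back-calculate extract concentrations to the sample frame
#'
#' Converts a concentration measured in the diluted analyte solution of a
#' solid-phase extract to the original sample frame, accounting for the
#' extract-to-sample volume ratio and the dilution through evaporation and
#' re-dissolution: `measured x dilution x v_extract / v_sample`.
#'
#' @param measured Concentration in the analysed solution (umol/L).
#' @param v_extract Extract volume (mL, e.g. 0.7).
#' @param v_sample Extracted sample volume (mL, e.g. 75).
#' @param dilution Net dilution factor of the analysed aliquot (default 1).
#' @return Sample-frame concentration (umol/L).
#' @export
#' @examples
#' spe_back_calculate(100, 0.7, 75, dilution = 100)  # ~93.3
spe_back_calculate <- function(measured, v_extract, v_sample, dilution = 1) {
  stopifnot(v_extract > 0, v_sample > 0, dilution > 0)
  measured * dilution * v_extract / v_sample
}

#' Reconstruct the initial-solution chemistry and DOM characteristics
#'
#' Convenience wrapper reproducing the full endmember reconstruction of an
#' incubation starting solution from plume and control endmembers: scalar
#' chemistry by volume-weighted mixing (with configurable control-replicate
#' inclusion masks per analyte), DOM characteristics by SPE-DOC-weighted
#' mixing, and the degradation index from 1:9-weighted intensity profiles
#' when profiles are supplied.
#'
#' @param plume_chem One-row data.frame of plume chemistry (columns `dfe`,
#'   `ligand_excess`, `doc`, `spe_doc`, `tdn`, `spe_tdn` as available).
#' @param control_chem data.frame of control replicate chemistry.
#' @param v_plume,v_control Mixing volumes (default 50 and 450 mL).
#' @param control_mask Named list mapping analyte column to the logical
#'   or integer subset of control replicates used for it (default: all
#'   replicates for every analyte except `dfe`, which uses the replicates
#'   not flagged as outliers via `control_chem$flag`).
#' @param plume_summary,control_summary Optional endmember DOM summaries for
#'   [mix_dom_characteristics()].
#' @param plume_profile,control_profile Optional raw intensity profiles for
#'   the mixed degradation index.
#' @param ideg_weights Profile weights, default c(plume = 1, control = 9).
#' @return List with `chemistry` (named vector), `dom` (named vector or
#'   NULL) and `ideg` (scalar or NULL).
#' @export
reconstruct_initial_solution <- function(plume_chem, control_chem,
                                         v_plume = 50, v_control = 450,
                                         control_mask = NULL,
                                         plume_summary = NULL,
                                         control_summary = NULL,
                                         plume_profile = NULL,
                                         control_profile = NULL,
                                         ideg_weights = c(1, 9)) {
  analytes <- intersect(c("dfe", "ligand_excess", "doc", "spe_doc", "tdn",
                          "spe_tdn"),
                        intersect(names(plume_chem), names(control_chem)))
  if (is.null(control_mask)) {
    not_outlier <- if ("flag" %in% names(control_chem)) {
      !grepl("star|outlier", ifelse(is.na(control_chem$flag), "",
                                    control_chem$flag))
    } else rep(TRUE, nrow(control_chem))
    control_mask <- list(dfe = which(not_outlier))
  }
  chem <- vapply(analytes, function(a) {
    rows <- control_mask[[a]] %||% seq_len(nrow(control_chem))
    vals <- control_chem[[a]][rows]
    vals <- vals[!is.na(vals)]
    if (!length(vals) || is.na(plume_chem[[a]][1])) return(NA_real_)
    mix_concentration(plume_chem[[a]][1], mean(vals), v_plume, v_control)
  }, numeric(1))
  dom <- NULL
  if (!is.null(plume_summary) && !is.null(control_summary)) {
    dom <- mix_dom_characteristics(plume_summary, control_summary,
                                   spe_doc_p = plume_chem$spe_doc[1],
                                   spe_doc_c = mean(control_chem$spe_doc,
                                                    na.rm = TRUE),
                                   v_plume = v_plume, v_control = v_control)
  }
  ideg_mix <- NULL
  if (!is.null(plume_profile) && !is.null(control_profile)) {
    mixed <- mix_intensity_profiles(plume_profile, control_profile,
                                    ideg_weights[1], ideg_weights[2])
    ideg_mix <- ideg(mixed)
  }
  list(chemistry = chem, dom = dom, ideg = ideg_mix)
}
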