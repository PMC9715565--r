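# Per-formula mass arithmetic and molecular indices.
#
# All functions are vectorised over the rows of a formula count table and
# accept formula strings as a convenience.

#' Monoisotopic neutral mass
#'
#' Sum of most-abundant-isotope masses (12C, 1H, 14N, 16O, 32S, 31P, 35Cl,
#' 56Fe) of the written composition, treated as the neutral molecule.
#'
#' @param ft Formula count table or character vector of formulas.
#' @return Numeric vector of masses in Da.
#' @export
#' @examples
#' monoisotopic_mass("H2O")  # 18.010565
monoisotopic_mass <- function(ft) {
  ft <- as_formula_table(ft)
  drop(as.matrix(ft) %*% element_masses()[ELEMENTS])
}

#' m/z of the singly deprotonated ion
#'
#' Negative-mode ESI convention: the \[M-H\]- ion of the neutral composition,
#' `monoisotopic_mass(f) - 1.00728` (proton mass with the electron mass
#' folded in).
#'
#' @inheritParams monoisotopic_mass
#' @return Numeric vector of ion m/z values in Da.
#' @export
#' @examples
#' round(mz_deprotonated("C20H23FeN3O2"))  # 392
mz_deprotonated <- function(ft) {
  ft <- as_formula_table(ft)
  if (any(ft$H < 1L, na.rm = TRUE))
    stop("cannot deprotonate a composition with no hydrogen")
  monoisotopic_mass(ft) - PROTON_MASS
}

#' Double bond equivalents
#'
#' `DBE = 1 + (2C - H + N + P) / 2`. Cl and Fe do not enter the sum.
#'
#' @inheritParams monoisotopic_mass
#' @return Numeric vector; `NA` where C = 0.
#' @export
#' @examples
#' dbe("C15H14O6")  # 9
dbe <- function(ft) {
  ft <- as_formula_table(ft)
  out <- 1 + 0.5 * (2 * ft$C - ft$H + ft$N + ft$P)
  out[ft$C < 1L] <- NA_real_
  out
}

#' Modified aromaticity index
#'
#' `AImod = (1 + C - O/2 - S - (N + P + H)/2) / (C - O/2 - S - N - P)`,
#' counting half the oxygen as carbonyl-like. Where the denominator is
#' nonpositive or the numerator negative the index is undefined and clamped
#' to 0 (no aromaticity), the community convention.
#'
#' @inheritParams monoisotopic_mass
#' @return Numeric vector in \[0, 1\] for CHNOSP compositions; `NA` where
#'   C = 0.
#' @export
#' @examples
#' aimod("C15H14O6")  # 0.5
aimod <- function(ft) {
  ft <- as_formula_table(ft)
  num <- 1 + ft$C - 0.5 * ft$O - ft$S - 0.5 * (ft$N + ft$P + ft$H)
  den <- ft$C - 0.5 * ft$O - ft$S - ft$N - ft$P
  out <- ifelse(den <= 0 | num < 0, 0, num / den)
  out[ft$C < 1L] <- NA_real_
  out
}

#' Nominal oxidation state of carbon
#'
#' `NOSC = 4 - (4C + H - 3N - 2O - 2S) / C`.
#'
#' @inheritParams monoisotopic_mass
#' @return Numeric vector; `NA` where C = 0.
#' @export
#' @examples
#' nosc("CH4")  # -4
nosc <- function(ft) {
  ft <- as_formula_table(ft)
  out <- 4 - (4 * ft$C + ft$H - 3 * ft$N - 2 * ft$O - 2 * ft$S) / ft$C
  out[ft$C < 1L] <- NA_real_
  out
}

#' Chemical plausibility of a neutral composition
#'
#' An even-electron neutral CHNOSP molecule must have an integer,
#' nonnegative double-bond-equivalent count: H + N + P even (nitrogen rule)
#' and `DBE >= 0`. Used to screen assignment candidates; the composition
#' grid itself is not restricted.
#'
#' @inheritParams monoisotopic_mass
#' @return Logical vector.
#' @export
#' @examples
#' chemically_plausible(c("C15H14O6", "C15H15O6"))  # TRUE FALSE
chemically_plausible <- function(ft) {
  ft <- as_formula_table(ft)
  (ft$H + ft$N + ft$P) %% 2L == 0L & dbe(ft) >= 0
}

#' Default van Krevelen class boundaries
#'
#' Boundary constants of the standard compound-class scheme used by
#' [classify_formulas()]. Override individual values via `...`.
#'
#' @param ... Name = value overrides (`aimod_aromatic`, `aimod_polyphenol`,
#'   `hc_unsaturated`, `hc_saturated`, `oc_sugar`, `oc_rich`).
#' @return Named list of boundaries.
#' @export
class_boundaries <- function(...) {
  b <- list(aimod_aromatic = 0.66, aimod_polyphenol = 0.5,
            hc_unsaturated = 1.5, hc_saturated = 2.0,
            oc_sugar = 0.9, oc_rich = 0.5)
  dots <- list(...)
  for (nm in names(dots)) {
    if (!nm %in% names(b)) stop("unknown boundary '", nm, "'")
    b[[nm]] <- dots[[nm]]
  }
  b
}

# fixed level order of the compound-class factor
COMPOUND_CLASSES <- c("saturated_fatty_sugar", "aromatic_other",
                      "polyphenol_like", "highly_unsaturated_O_rich",
                      "highly_unsaturated_O_poor", "unsaturated_aliphatic",
                      "peptide_like")

#' Van Krevelen compound classification
#'
#' Assigns every composition exactly one of seven molecular groups from
#' (AImod, H/C, O/C, N), checked in a fixed order: saturated fatty acids and
#' sugars (H/C >= 2 or O/C >= 0.9) first, then polyaromatics
#' (AImod > 0.66), polyphenol-like (0.5 <= AImod <= 0.66), highly
#' unsaturated compounds (H/C < 1.5), split O-rich/O-poor at O/C = 0.5, and
#' finally aliphatics (H/C >= 1.5) split into peptide-like (N > 0) and
#' unsaturated aliphatics (N = 0).
#'
#' @inheritParams monoisotopic_mass
#' @param boundaries Output of [class_boundaries()].
#' @return Factor with levels [COMPOUND_CLASSES].
#' @export
#' @examples
#' classify_formulas("C15H14O6")  # polyphenol_like
classify_formulas <- function(ft, boundaries = class_boundaries()) {
  ft <- as_formula_table(ft)
  hc <- ft$H / ft$C
  oc <- ft$O / ft$C
  ai <- aimod(ft)
  b <- boundaries
  cls <- rep(NA_character_, nrow(ft))
  cls[hc >= b$hc_saturated | oc >= b$oc_sugar] <- "saturated_fatty_sugar"
  todo <- is.na(cls)
  cls[todo & ai > b$aimod_aromatic] <- "aromatic_other"
  todo <- is.na(cls)
  cls[todo & ai >= b$aimod_polyphenol] <- "polyphenol_like"
  todo <- is.na(cls)
  cls[todo & hc < b$hc_unsaturated & oc >= b$oc_rich] <- "highly_unsaturated_O_rich"
  todo <- is.na(cls)
  cls[todo & hc < b$hc_unsaturated] <- "highly_unsaturated_O_poor"
  todo <- is.na(cls)
  cls[todo & ft$N > 0L] <- "peptide_like"
  cls[is.na(cls)] <- "unsaturated_aliphatic"
  factor(cls, levels = COMPOUND_CLASSES)
}

#' Annotate a formula set
#'
#' Derives every per-formula quantity the downstream modules use: neutral
#' monoisotopic mass, \[M-H\]- m/z, DBE, AImod, NOSC, H/C, O/C, compound
#' class and an iron flag.
#'
#' @inheritParams monoisotopic_mass
#' @param boundaries Class boundaries, see [class_boundaries()].
#' @return data.frame: the count columns plus `formula`, `neutral_mass`,
#'   `mz_mh`, `dbe`, `aimod`, `nosc`, `h_c`, `o_c`, `compound_class`,
#'   `is_fe`.
#' @export
#' @examples
#' annotate_formulas(c("C15H14O6", "C20H23FeN3O2"))
annotate_formulas <- function(ft, boundaries = class_boundaries()) {
  ft <- as_formula_table(ft)
  data.frame(
    formula = format_formula(ft),
    ft,
    neutral_mass = monoisotopic_mass(ft),
    mz_mh = ifelse(ft$H >= 1L, monoisotopic_mass(ft) - PROTON_MASS, NA_real_),
    dbe = dbe(ft),
    aimod = aimod(ft),
    nosc = nosc(ft),
    h_c = ft$H / ft$C,
    o_c = ft$O / ft$C,
    compound_class = classify_formulas(ft, boundaries),
    is_fe = ft$Fe > 0L,
    stringsAsFactors = FALSE
  )
}
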