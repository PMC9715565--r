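# Physical constants and index-formula definitions.
#
# Element masses are shipped as a versioned table under inst/extdata so the
# provenance of every mass used in assignment is inspectable and replaceable.

# element order used throughout for count matrices
ELEMENTS <- c("C", "H", "N", "O", "S", "P", "Cl", "Fe")

# proton mass with the electron mass folded in: the standard convention for
# singly deprotonated ions in negative-mode ESI
PROTON_MASS <- 1.00728

# 13C - 12C mass difference, used for isotopologue verification
C13_DELTA <- 1.0033548

# natural 13C/12C abundance ratio per carbon atom
C13_ABUNDANCE <- 0.011

# degradation-index formulae: intensities of the NEG set rise with
# radiocarbon age of marine DOM, the POS set falls; I_DEG = NEG/(NEG+POS)
IDEG_NEG <- c("C21H26O11", "C17H20O9", "C19H22O10", "C20H22O10", "C20H24O11")
IDEG_POS <- c("C13H18O7", "C14H20O7", "C15H22O7", "C15H22O8", "C16H24O8")

#' Monoisotopic element masses
#'
#' Returns the table of most-abundant-isotope masses used for all mass
#' arithmetic, read once from the versioned file shipped with the package.
#'
#' @return Named numeric vector (Da) over elements C, H, N, O, S, P, Cl, Fe.
#' @export
#' @examples
#' element_masses()[["O"]]
element_masses <- function() {
  if (is.null(the$masses)) {
    path <- system.file("extdata", "monoisotopic_masses.csv", package = "ferrodom")
    tab <- read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
    the$masses <- setNames(tab$mass_da, tab$element)[ELEMENTS]
  }
  the$masses
}

#' Degradation-index formulae
#'
#' The ten index compositions whose raw intensities define the degradation
#' index: `neg` intensities increase with DOM age, `pos` decrease.
#'
#' @return List with character vectors `neg` and `pos`.
#' @export
ideg_formulas <- function() list(neg = IDEG_NEG, pos = IDEG_POS)

#' Default known-contaminant formulae
#'
#' Reads the editable contaminant list shipped with the package (surfactants,
#' plasticizers and similar lab background compositions).
#'
#' @param path Optional path to an alternative list (one formula per line,
#'   `#` starts a comment).
#' @return Character vector of canonical formula strings.
#' @export
default_contaminants <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "contaminants.txt", package = "ferrodom")
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  toks <- vapply(strsplit(lines[nzchar(lines)], "[[:space:]]+"), `[[`, "", 1L)
  unname(toks)
}
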