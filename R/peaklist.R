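# Peak list container: one replicate FT-ICR-MS measurement.

#' Construct a peak list
#'
#' A peak list holds the centroided (m/z, intensity) pairs of one replicate
#' measurement together with its sample metadata. Peaks are stored sorted by
#' m/z; duplicate m/z values (within 1e-6 Da) and nonpositive intensities are
#' rejected.
#'
#' @param mz Numeric vector of ion m/z values (Da).
#' @param intensity Numeric vector of positive intensities (arbitrary units).
#' @param sample_id,replicate_id Identifiers of the sample and the
#'   measurement replicate.
#' @param is_blank Logical; TRUE for solvent/procedural blank measurements.
#' @return Object of class `peaklist`: a data.frame with columns `mz` and
#'   `intensity` and attributes `sample_id`, `replicate_id`, `is_blank`.
#' @export
#' @examples
#' peaklist(c(212.1, 213.2), c(1e6, 2e5), "S1", 1)
peaklist <- function(mz, intensity, sample_id = "sample", replicate_id = 1L,
                     is_blank = FALSE) {
  if (length(mz) != length(intensity))
    stop("mz and intensity lengths differ")
  if (any(!is.finite(mz)) || any(!is.finite(intensity)))
    stop("non-finite m/z or intensity")
  if (any(intensity <= 0))
    stop("intensities must be positive")
  ord <- order(mz)
  mz <- mz[ord]; intensity <- intensity[ord]
  if (any(diff(mz) < 1e-6))
    stop("duplicate m/z values within instrument resolution")
  out <- data.frame(mz = mz, intensity = intensity)
  attr(out, "sample_id") <- as.character(sample_id)
  attr(out, "replicate_id") <- as.character(replicate_id)
  attr(out, "is_blank") <- isTRUE(is_blank)
  class(out) <- c("peaklist", "data.frame")
  out
}

#' @export
print.peaklist <- function(x, ...) {
  cat(sprintf("<peaklist> sample %s, replicate %s%s: %d peaks, m/z %.4f-%.4f\n",
              attr(x, "sample_id"), attr(x, "replicate_id"),
              if (isTRUE(attr(x, "is_blank"))) " (blank)" else "",
              nrow(x), min(x$mz), max(x$mz)))
  invisible(x)
}

# rebuild a peaklist after filtering rows, keeping metadata
peaklist_like <- function(template, mz, intensity) {
  peaklist(mz, intensity,
           sample_id = attr(template, "sample_id"),
           replicate_id = attr(template, "replicate_id"),
           is_blank = attr(template, "is_blank"))
}

#' Restrict a peak list to an m/z window
#'
#' @param pl A [peaklist()].
#' @param range Length-2 numeric window in Da (default the acquisition
#'   window 50-1000).
#' @return Filtered peaklist.
#' @export
filter_mz_range <- function(pl, range = c(50, 1000)) {
  keep <- pl$mz >= range[1] & pl$mz <= range[2]
  peaklist_like(pl, pl$mz[keep], pl$intensity[keep])
}
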