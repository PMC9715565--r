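# Post-assignment data reduction cascade.
#
# Fixed stage order: elemental rules -> blank subtraction -> spectral
# smoothing -> replicate intersection -> known contaminants -> minimum
# sample occurrence. The cascade is idempotent and every row removal is
# attributed to exactly one rule in the removal log.

#' Elemental plausibility filters
#'
#' Removes formula rows violating any of the composition restrictions
#' C >= O; O > 2P + S; H <= 2C + 2; N <= 6; S <= 2; P <= 1. Each removed row
#' is attributed to the first rule it violates (in that order).
#'
#' @param ct A [dom_crosstable()].
#' @return Filtered cross table; removals appear in [removal_log()].
#' @export
elemental_filters <- function(ct) {
  f <- ct$annotation
  rules <- list(
    "C >= O"      = f$C >= f$O,
    "O > 2P + S"  = f$O > 2 * f$P + f$S,
    "H <= 2C + 2" = f$H <= 2 * f$C + 2,
    "N <= 6"      = f$N <= 6,
    "S <= 2"      = f$S <= 2,
    "P <= 1"      = f$P <= 1
  )
  violated <- rep(NA_character_, nrow(f))
  for (nm in names(rules))
    violated[is.na(violated) & !rules[[nm]]] <- nm
  out <- ct_subset(ct, rows = is.na(violated))
  for (nm in names(rules))
    out <- log_removal(out, "elemental", nm, sum(violated == nm, na.rm = TRUE))
  out
}

#' Blank subtraction
#'
#' A formula detected in the solvent/procedural blanks is deleted from a
#' sample column when the sample intensity does not exceed `factor` times
#' the maximum blank intensity of that formula. Rows left without any
#' nonzero cell are removed.
#'
#' @param ct A [dom_crosstable()] of sample measurements.
#' @param blanks A [dom_crosstable()] built from blank measurements, or a
#'   named numeric vector of per-formula blank intensities.
#' @param factor Comparison factor (default 1: sample <= blank deletes).
#' @return Filtered cross table.
#' @export
blank_filter <- function(ct, blanks, factor = 1) {
  blank_max <- if (inherits(blanks, "dom_crosstable")) {
    apply(blanks$intensity, 1L, max)
  } else {
    blanks
  }
  shared <- intersect(rownames(ct$intensity), names(blank_max))
  int <- ct$intensity
  n_cells <- 0L
  if (length(shared)) {
    b <- blank_max[shared]
    sub <- int[shared, , drop = FALSE]
    kill <- sub > 0 & sub <= factor * b
    n_cells <- sum(kill)
    sub[kill] <- 0
    int[shared, ] <- sub
  }
  out <- ct
  out$intensity <- int
  keep <- rowSums(int > 0) > 0
  out <- ct_subset(out, rows = keep)
  out <- log_removal(out, "blank", sprintf("deleted cells (<= %g x blank)", factor),
                     n_cells)
  log_removal(out, "blank", "rows fully blanked", sum(!keep))
}

#' Spectral smoothing filter
#'
#' Within each column, formulas are ordered by neutral mass and a cell is
#' removed when its intensity exceeds `factor` times the maximum intensity
#' among the up to `window` detected neighbours on each side (truncated at
#' the spectrum edges). Removes isolated intensity spikes that violate the
#' near-Gaussian local envelope of DOM spectra.
#'
#' @param ct A [dom_crosstable()].
#' @param factor Spike factor (default 2).
#' @param window Number of neighbouring formulas per side (default 10).
#' @return Filtered cross table.
#' @export
spectral_smoothing_filter <- function(ct, factor = 2, window = 10L) {
  int <- ct$intensity
  mass <- ct$annotation$neutral_mass
  n_cells <- 0L
  for (j in seq_len(ncol(int))) {
    nz <- which(int[, j] > 0)
    if (length(nz) < 2L) next
    nz <- nz[order(mass[nz])]
    x <- int[nz, j]
    n <- length(x)
    for (i in seq_len(n)) {
      lo <- max(1L, i - window); hi <- min(n, i + window)
      nb <- x[setdiff(lo:hi, i)]
      if (length(nb) && x[i] > factor * max(nb)) {
        int[nz[i], j] <- 0
        n_cells <- n_cells + 1L
      }
    }
  }
  out <- ct
  out$intensity <- int
  keep <- rowSums(int > 0) > 0
  out <- ct_subset(out, rows = keep)
  out <- log_removal(out, "smoothing",
                     sprintf("spike cells (> %g x local max)", factor), n_cells)
  log_removal(out, "smoothing", "rows fully removed", sum(rowSums(ct$intensity > 0) > 0) - sum(keep))
}

#' Merge measurement replicates
#'
#' For every sample, only formulas detected in all of its replicated
#' measurements remain, with the arithmetic mean intensity assigned. Samples
#' with a single measurement pass through unchanged and are flagged in the
#' result's meta (`merge_warning`), with a warning.
#'
#' @param ct A [dom_crosstable()] whose meta maps columns to samples.
#' @return Cross table with one column per sample.
#' @export
merge_replicates <- function(ct) {
  samples <- unique(ct$meta$sample_id)
  int <- matrix(0, nrow = nrow(ct$intensity), ncol = length(samples),
                dimnames = list(rownames(ct$intensity), samples))
  warn <- logical(length(samples))
  grp <- character(length(samples))
  for (k in seq_along(samples)) {
    cols <- which(ct$meta$sample_id == samples[k])
    sub <- ct$intensity[, cols, drop = FALSE]
    if (length(cols) == 1L) {
      int[, k] <- sub[, 1L]
      warn[k] <- TRUE
    } else {
      both <- rowSums(sub > 0) == length(cols)
      int[both, k] <- rowMeans(sub[both, , drop = FALSE])
    }
    grp[k] <- as.character(ct$meta$group[cols[1L]])
  }
  if (any(warn))
    warning("sample(s) without replicate measurement passed through unmerged: ",
            paste(samples[warn], collapse = ", "))
  meta <- data.frame(column = samples, sample_id = samples,
                     replicate_id = "merged", group = grp,
                     merge_warning = warn, stringsAsFactors = FALSE)
  keep <- rowSums(int > 0) > 0
  out <- dom_crosstable(int[keep, , drop = FALSE], meta)
  attr(out, "removal_log") <- attr(ct, "removal_log")
  log_removal(out, "replicate_merge", "not in all measurement replicates",
              sum(!keep))
}

#' Remove known contaminant formulas
#'
#' @param ct A [dom_crosstable()].
#' @param contaminants Character vector of formula strings (default the
#'   shipped list, see [default_contaminants()]).
#' @return Filtered cross table.
#' @export
contaminant_filter <- function(ct, contaminants = default_contaminants()) {
  hit <- rownames(ct$intensity) %in% contaminants
  out <- ct_subset(ct, rows = !hit)
  log_removal(out, "contaminants", "known contaminant list", sum(hit))
}

#' Minimum sample occurrence filter
#'
#' Keeps only formulas detected in at least `min_samples` different sample
#' columns.
#'
#' @param ct A [dom_crosstable()] (after replicate merging).
#' @param min_samples Minimum number of samples (default 2).
#' @return Filtered cross table.
#' @export
min_sample_filter <- function(ct, min_samples = 2L) {
  keep <- rowSums(ct$intensity > 0) >= min_samples
  out <- ct_subset(ct, rows = keep)
  log_removal(out, "min_sample",
              sprintf("in fewer than %d samples", min_samples), sum(!keep))
}

#' Run the full reduction cascade
#'
#' Applies, in fixed order: [elemental_filters()], [blank_filter()] (when
#' blanks are given), [spectral_smoothing_filter()], [merge_replicates()],
#' [contaminant_filter()], [min_sample_filter()]. Re-running the cascade on
#' its own output changes nothing.
#'
#' @param ct A [dom_crosstable()] of per-measurement assignments.
#' @param blanks Optional blank cross table or named intensity vector.
#' @param contaminants Contaminant formula list.
#' @param blank_factor,smooth_factor,smooth_window,min_samples Stage
#'   parameters, see the individual functions.
#' @param merge Merge measurement replicates into samples (default TRUE; set
#'   FALSE when `ct` already holds one column per sample).
#' @return Reduced cross table carrying the complete [removal_log()].
#' @export
reduce_crosstable <- function(ct, blanks = NULL,
                              contaminants = default_contaminants(),
                              blank_factor = 1, smooth_factor = 2,
                              smooth_window = 10L, min_samples = 2L,
                              merge = TRUE) {
  out <- elemental_filters(ct)
  if (!is.null(blanks))
    out <- blank_filter(out, blanks, factor = blank_factor)
  out <- spectral_smoothing_filter(out, factor = smooth_factor,
                                   window = smooth_window)
  if (merge)
    out <- merge_replicates(out)
  out <- contaminant_filter(out, contaminants)
  min_sample_filter(out, min_samples)
}

#' Section intersection across replicate samples
#'
#' The "section" dataset of an experimental group keeps only formulas
#' occurring in all replicate samples of that group, with averaged
#' intensity.
#'
#' @param ct A merged [dom_crosstable()] (one column per sample) whose meta
#'   `group` assigns samples to groups.
#' @param groups Optional explicit group vector (one entry per column).
#' @return Cross table with one column per group.
#' @export
section_intersect <- function(ct, groups = ct$meta$group) {
  groups <- as.character(groups)
  gl <- unique(groups)
  int <- matrix(0, nrow = nrow(ct$intensity), ncol = length(gl),
                dimnames = list(rownames(ct$intensity), gl))
  for (k in seq_along(gl)) {
    cols <- which(groups == gl[k])
    sub <- ct$intensity[, cols, drop = FALSE]
    all_in <- rowSums(sub > 0) == length(cols)
    int[all_in, k] <- rowMeans(sub[all_in, , drop = FALSE])
  }
  keep <- rowSums(int > 0) > 0
  meta <- data.frame(column = gl, sample_id = gl, replicate_id = "section",
                     group = gl, stringsAsFactors = FALSE)
  out <- dom_crosstable(int[keep, , drop = FALSE], meta)
  attr(out, "removal_log") <- attr(ct, "removal_log")
  out
}

#' Keep the top-n formulas per sample and normalise
#'
#' Per column the `n` highest intensities are kept (ties resolved in favour
#' of the lower-mass formula) and the column is divided by its sum, so
#' every retained column sums to 1.
#'
#' @param ct A [dom_crosstable()].
#' @param n Number of formulas kept per column (default 1000).
#' @return Normalised cross table (attribute `normalized` set).
#' @export
top_n_normalize <- function(ct, n = 1000L) {
  int <- ct$intensity
  mass <- ct$annotation$neutral_mass
  for (j in seq_len(ncol(int))) {
    nz <- which(int[, j] > 0)
    if (length(nz) > n) {
      ord <- nz[order(-int[nz, j], mass[nz])]
      int[ord[-seq_len(n)], j] <- 0
    }
    s <- sum(int[, j])
    if (s > 0) int[, j] <- int[, j] / s
  }
  keep <- rowSums(int > 0) > 0
  out <- ct
  out$intensity <- int
  out <- ct_subset(out, rows = keep)
  attr(out, "normalized") <- TRUE
  out
}

#' Sample-level quality-control flags
#'
#' Flags samples whose SPE extract chemistry or DOM summary indicates a
#' problem: `contaminated` when SPE-TDN exceeds TDN (nitrogen contamination
#' of the extract) and `outlier` when, within a group of at least three
#' replicates, a replicate's average m/z deviates from the mean of the
#' others by more than `outlier_threshold` (relative).
#'
#' @param chem data.frame with columns `sample`, `tdn`, `spe_tdn` (and
#'   optionally `group`).
#' @param summaries Optional data.frame with `sample`, `group`, `mz`
#'   (per-replicate average mass) for outlier detection.
#' @param outlier_threshold Relative deviation threshold (default 0.05).
#' @return data.frame with `sample`, `contaminated`, `outlier`.
#' @export
qc_flags <- function(chem, summaries = NULL, outlier_threshold = 0.05) {
  out <- data.frame(sample = chem$sample,
                    contaminated = !is.na(chem$spe_tdn) & !is.na(chem$tdn) &
                      chem$spe_tdn > chem$tdn,
                    outlier = FALSE, stringsAsFactors = FALSE)
  if (!is.null(summaries)) {
    for (g in unique(summaries$group)) {
      rows <- which(summaries$group == g)
      if (length(rows) < 3L) next
      for (i in rows) {
        others <- setdiff(rows, i)
        ref <- mean(summaries$mz[others])
        spread <- diff(range(summaries$mz[others])) / ref
        # a replicate is an outlier only when the remaining replicates agree
        # among themselves and it deviates from them
        if (is.finite(ref) && ref > 0 && spread <= outlier_threshold &&
            abs(summaries$mz[i] - ref) / ref > outlier_threshold) {
          out$outlier[out$sample == summaries$sample[i]] <- TRUE
        }
      }
    }
  }
  out
}
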