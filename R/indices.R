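# Per-sample intensity-weighted DOM characteristics and diversity indices.

#' Degradation index
#'
#' Ratio of the summed raw intensities of the five age-positive ("degraded")
#' index formulas to the summed intensities of all ten index formulas,
#' `I_DEG = sum(NEG) / (sum(NEG) + sum(POS))`: 0 = fresh, 1 = fully
#' degraded signature. Computed on raw (pre-normalisation) intensities;
#' absent index formulas contribute 0. `NA` (with a warning) when none of
#' the ten formulas is present.
#'
#' @param intensities Named numeric vector (names = formula strings) or a
#'   single cross-table column extracted with names.
#' @return Scalar in \[0, 1\] or `NA`.
#' @export
#' @examples
#' ideg(setNames(rep(1, 10), unlist(ideg_formulas())))  # 0.5
ideg <- function(intensities) {
  neg <- sum(intensities[names(intensities) %in% IDEG_NEG], na.rm = TRUE)
  pos <- sum(intensities[names(intensities) %in% IDEG_POS], na.rm = TRUE)
  if (neg + pos <= 0) {
    warning("no degradation-index formula present; I_DEG undefined")
    return(NA_real_)
  }
  neg / (neg + pos)
}

#' Rao's-entropy functional diversity
#'
#' `D_F(c) = sum_{i<j} p_i p_j |c_i - c_j|` for relative intensities `p`
#' and a per-formula characteristic `c` (carbon number, H/C or NOSC).
#' Computed via the sorted closed form
#' `sum_k (c_(k+1) - c_(k)) F_k (1 - F_k)` with `F` the cumulative
#' intensity share, which equals the O(N^2) pair sum exactly.
#'
#' @param p Nonnegative weights; normalised to sum to 1 internally.
#' @param c Characteristic values, same length as `p`.
#' @return Scalar diversity (0 for a single formula).
#' @export
#' @examples
#' rao_entropy(c(0.2, 0.3, 0.5), c(1, 2, 4))  # 0.66
rao_entropy <- function(p, c) {
  if (length(p) != length(c)) stop("p and c lengths differ")
  keep <- p > 0 & is.finite(c)
  p <- p[keep]; c <- c[keep]
  if (length(p) < 2L) return(0)
  p <- p / sum(p)
  ord <- order(c)
  c <- c[ord]; p <- p[ord]
  F <- cumsum(p)[-length(p)]
  sum(diff(c) * F * (1 - F))
}

#' Gini-Simpson diversity
#'
#' `D_A = 1 - sum(p_i^2)` on relative intensities.
#'
#' @param p Nonnegative weights; normalised internally.
#' @return Scalar in \[0, 1).
#' @export
gini_simpson <- function(p) {
  p <- p[p > 0]
  p <- p / sum(p)
  1 - sum(p^2)
}

#' Intensity-weighted DOM summary of samples
#'
#' For every column of a cross table computes the intensity-weighted mean
#' molecular characteristics (m/z of the \[M-H\]- ion, H/C, O/C, AImod, DBE,
#' NOSC), formula richness, iron-formula count, the degradation index (on
#' the raw column intensities), Rao functional diversities over carbon
#' number, H/C and NOSC, the Gini-Simpson index, and compound-class
#' fractions (intensity-weighted; count-based fractions are attached as an
#' attribute).
#'
#' @param ct A [dom_crosstable()] (the full, not top-n, dataset).
#' @return data.frame with one row per column, in the column order
#'   m/z, H/C, O/C, AImod, DBE, NOSC, I_DEG, number of formulas, D_F(C),
#'   D_F(H/C), D_F(NOSC), number of Fe formulas, D_A, then class fractions.
#' @export
dom_summary <- function(ct) {
  ann <- ct$annotation
  int <- ct$intensity
  cols <- colnames(int)
  classes <- levels(ann$compound_class)
  out <- data.frame(sample = cols, mz = NA_real_, h_c = NA_real_,
                    o_c = NA_real_, aimod = NA_real_, dbe = NA_real_,
                    nosc = NA_real_, ideg = NA_real_,
                    n_formulas = NA_integer_, df_c = NA_real_,
                    df_hc = NA_real_, df_nosc = NA_real_,
                    n_fe_formulas = NA_integer_, da = NA_real_,
                    stringsAsFactors = FALSE)
  frac_int <- matrix(NA_real_, length(cols), length(classes),
                     dimnames = list(cols, classes))
  frac_cnt <- frac_int
  for (j in seq_along(cols)) {
    x <- int[, j]
    nz <- x > 0
    if (!any(nz)) {
      warning("column '", cols[j], "' has no intensity; summary undefined")
      next
    }
    p <- x[nz] / sum(x[nz])
    a <- ann[nz, , drop = FALSE]
    out$mz[j] <- sum(p * a$mz_mh)
    out$h_c[j] <- sum(p * a$h_c)
    out$o_c[j] <- sum(p * a$o_c)
    out$aimod[j] <- sum(p * a$aimod)
    out$dbe[j] <- sum(p * a$dbe)
    out$nosc[j] <- sum(p * a$nosc)
    out$ideg[j] <- suppressWarnings(ideg(setNames(x[nz], rownames(a))))
    out$n_formulas[j] <- sum(nz)
    out$df_c[j] <- rao_entropy(p, a$C)
    out$df_hc[j] <- rao_entropy(p, a$h_c)
    out$df_nosc[j] <- rao_entropy(p, a$nosc)
    out$n_fe_formulas[j] <- sum(a$is_fe)
    out$da[j] <- gini_simpson(p)
    frac_int[j, ] <- vapply(classes, function(cl)
      sum(p[a$compound_class == cl]), numeric(1))
    frac_cnt[j, ] <- vapply(classes, function(cl)
      mean(a$compound_class == cl), numeric(1))
  }
  res <- cbind(out, as.data.frame(frac_int))
  attr(res, "class_fractions_by_count") <- as.data.frame(frac_cnt)
  rownames(res) <- NULL
  res
}
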