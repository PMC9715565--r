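# Sample dissimilarity, ordination, and formula-covariate correlation
# screens.

#' Bray-Curtis dissimilarity between samples
#'
#' `d(a, b) = sum|a_i - b_i| / sum(a_i + b_i)` over the formula intensities
#' of two sample columns, computed with vegan. Pairs of all-zero columns are
#' undefined and returned as `NA` with a warning.
#'
#' @param ct A [dom_crosstable()] (normalised columns recommended).
#' @return Symmetric matrix of dissimilarities with zero diagonal.
#' @export
bray_curtis <- function(ct) {
  m <- t(ct$intensity)
  empty <- rowSums(m) == 0
  d <- as.matrix(suppressWarnings(vegan::vegdist(m, method = "bray")))
  if (any(empty)) {
    warning("all-zero sample column(s): ", paste(rownames(m)[empty],
                                                 collapse = ", "))
    d[empty, ] <- NA; d[, empty] <- NA
  }
  diag(d) <- 0
  d
}

#' Principal coordinate analysis
#'
#' Classical (metric) multidimensional scaling of a dissimilarity matrix by
#' double-centring -d^2/2. Axes are ordered by eigenvalue; axes with
#' negative eigenvalues (Bray-Curtis is semimetric) are dropped and their
#' magnitude share reported.
#'
#' @param d Square symmetric dissimilarity matrix with zero diagonal.
#' @return List of class `dom_pcoa`: `coordinates` (samples x retained
#'   axes), `eigenvalues`, `variance_explained` (shares over positive
#'   eigenvalues), `negative_share`.
#' @export
dom_pcoa <- function(d) {
  d <- as.matrix(d)
  if (nrow(d) != ncol(d) || any(abs(d - t(d)) > 1e-8, na.rm = TRUE))
    stop("dissimilarity matrix must be square and symmetric")
  fit <- cmdscale(stats::as.dist(d), k = nrow(d) - 1L, eig = TRUE)
  eig <- fit$eig
  pos <- which(eig > 1e-8 * max(abs(eig)))
  coords <- fit$points[, seq_along(pos), drop = FALSE]
  colnames(coords) <- paste0("PCo", seq_along(pos))
  structure(list(
    coordinates = coords,
    eigenvalues = eig[pos],
    variance_explained = eig[pos] / sum(eig[pos]),
    negative_share = sum(abs(eig[eig < 0])) / sum(abs(eig))
  ), class = "dom_pcoa")
}

#' @export
print.dom_pcoa <- function(x, ...) {
  cat(sprintf("<dom_pcoa> %d samples, %d retained axes; axis 1-2 explain %.1f%% + %.1f%%\n",
              nrow(x$coordinates), ncol(x$coordinates),
              100 * x$variance_explained[1],
              100 * (if (length(x$variance_explained) > 1)
                x$variance_explained[2] else 0)))
  invisible(x)
}

# Spearman rank correlation with average ranks; p two-sided via the
# t approximation for n >= 10 and by permutation below (exact when all n!
# orderings are enumerable, Monte Carlo otherwise) -- incubation screens
# often have very few samples.
spearman_screen <- function(x, y, n_perm = 10000L, exact_max = 7L) {
  r <- cor(rank(x), rank(y))
  n <- length(x)
  if (!is.finite(r)) return(c(r = NA_real_, p = NA_real_))
  if (n >= 10L) {
    tstat <- r * sqrt((n - 2) / max(1 - r^2, .Machine$double.eps))
    p <- 2 * pt(-abs(tstat), n - 2)
  } else if (n <= exact_max) {
    perms <- all_permutations(n)
    rx <- rank(x); ry <- rank(y)
    rp <- apply(perms, 1L, function(idx) cor(rx, ry[idx]))
    p <- mean(abs(rp) >= abs(r) - 1e-12)
  } else {
    ry <- rank(y); rx <- rank(x)
    rp <- vapply(seq_len(n_perm), function(i) cor(rx, sample(ry)), numeric(1))
    p <- (1 + sum(abs(rp) >= abs(r) - 1e-12)) / (n_perm + 1)
  }
  c(r = r, p = min(p, 1))
}

# all permutations of 1..n as a matrix (n! rows); n is small by construction
all_permutations <- function(n) {
  if (n == 1L) return(matrix(1L, 1L, 1L))
  sub <- all_permutations(n - 1L)
  out <- matrix(0L, nrow = n * nrow(sub), ncol = n)
  row <- 1L
  for (pos in seq_len(n)) {
    for (i in seq_len(nrow(sub))) {
      perm <- integer(n)
      perm[pos] <- n
      perm[-pos] <- sub[i, ]
      out[row, ] <- perm
      row <- row + 1L
    }
  }
  out
}

#' Formula-covariate correlation screen
#'
#' Correlates every formula's relative intensity across samples with every
#' covariate (microbial group relative abundances and similar). Hits are
#' retained at `p < alpha` and, for the Spearman screen, `|r| > r_cutoff`.
#' Every hit is annotated with whether the formula is also significantly
#' correlated with the iron gradient at the same thresholds
#' (`fe_confounded`), the basis of the unconfounded highlight rule. No
#' multiple-testing correction is applied by default; Benjamini-Hochberg is
#' available via `adjust = "BH"`.
#'
#' @param ct A top-n normalised [dom_crosstable()].
#' @param covariates data.frame: rownames (or a `sample` column) matching
#'   cross-table columns, numeric covariate columns.
#' @param fe Numeric vector of iron concentrations per sample (umol/L);
#'   screened as log10(fe + 1). When NULL, confounding is not assessed.
#' @param method "spearman" (default) or "pearson".
#' @param alpha Significance threshold (default 0.05).
#' @param r_cutoff Minimum |r| for spearman hits (default 0.5; 0 for
#'   pearson).
#' @param adjust "none" (default) or "BH".
#' @return data.frame of hits: `formula`, `covariate`, `method`, `r`, `p`,
#'   `fe_confounded`, plus `h_c`, `o_c`, `compound_class` for van Krevelen
#'   plotting. Attribute `skipped` lists constant formula vectors.
#' @export
correlate_formulae <- function(ct, covariates, fe = NULL,
                               method = c("spearman", "pearson"),
                               alpha = 0.05, r_cutoff = NULL,
                               adjust = c("none", "BH")) {
  method <- match.arg(method)
  adjust <- match.arg(adjust)
  if (is.null(r_cutoff))
    r_cutoff <- if (method == "spearman") 0.5 else 0
  if ("sample" %in% names(covariates)) {
    rownames(covariates) <- covariates$sample
    covariates$sample <- NULL
  }
  shared <- intersect(colnames(ct$intensity), rownames(covariates))
  if (length(shared) < 4L)
    stop("need at least 4 shared samples between cross table and covariates")
  int <- ct$intensity[, shared, drop = FALSE]
  cov <- covariates[shared, , drop = FALSE]
  if (!is.null(fe)) {
    if (is.null(names(fe))) names(fe) <- rownames(covariates)
    fe <- log10(fe[shared] + 1)
  }
  keep <- apply(int, 1L, function(v) sd(v) > 0)
  skipped <- rownames(int)[!keep]
  int <- int[keep, , drop = FALSE]
  one <- function(x, y) {
    if (method == "spearman") spearman_screen(x, y)
    else {
      ct_ <- cor.test(x, y, method = "pearson")
      c(r = unname(ct_$estimate), p = ct_$p.value)
    }
  }
  fe_conf <- rep(FALSE, nrow(int))
  if (!is.null(fe)) {
    fe_rp <- t(apply(int, 1L, one, y = fe))
    fe_p <- if (adjust == "BH") stats::p.adjust(fe_rp[, "p"], "BH") else fe_rp[, "p"]
    fe_conf <- fe_p < alpha & abs(fe_rp[, "r"]) > r_cutoff
  }
  hits <- list()
  for (cv in names(cov)) {
    y <- cov[[cv]]
    rp <- t(apply(int, 1L, one, y = y))
    p <- if (adjust == "BH") stats::p.adjust(rp[, "p"], "BH") else rp[, "p"]
    sel <- which(p < alpha & abs(rp[, "r"]) > r_cutoff)
    if (length(sel))
      hits[[cv]] <- data.frame(formula = rownames(int)[sel], covariate = cv,
                               method = method, r = unname(rp[sel, "r"]),
                               p = unname(p[sel]),
                               fe_confounded = unname(fe_conf[sel]),
                               stringsAsFactors = FALSE)
  }
  out <- if (length(hits)) do.call(rbind, c(hits, make.row.names = FALSE))
  else data.frame(formula = character(0), covariate = character(0),
                  method = character(0), r = numeric(0), p = numeric(0),
                  fe_confounded = logical(0))
  ann <- ct$annotation[out$formula, c("h_c", "o_c", "compound_class")]
  out <- cbind(out, ann)
  rownames(out) <- NULL
  attr(out, "skipped") <- skipped
  out
}

#' Keep hits not confounded by the iron gradient
#'
#' Formulas whose covariate correlation survives after requiring no
#' simultaneous significant correlation with Fe: the candidates for a
#' genuine microbial association.
#'
#' @param hits Output of [correlate_formulae()].
#' @return Subset of `hits` with `fe_confounded == FALSE`.
#' @export
highlight_unconfounded <- function(hits) {
  hits[!hits$fe_confounded, , drop = FALSE]
}
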