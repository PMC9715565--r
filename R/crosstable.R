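# Formula x sample intensity cross table, the pipeline's central matrix.

#' Construct a formula cross table
#'
#' @param intensity Numeric matrix, rows = formulas (rownames are canonical
#'   formula strings), columns = measurement or sample columns; 0 = absent.
#' @param meta data.frame describing the columns; must contain `column`,
#'   `sample_id`; `replicate_id` and `group` (e.g. Fe level) are used by
#'   replicate merging and section intersection.
#' @return Object of class `dom_crosstable`: list with `intensity`,
#'   `annotation` (see [annotate_formulas()]) and `meta`.
#' @export
dom_crosstable <- function(intensity, meta) {
  intensity <- as.matrix(intensity)
  if (is.null(rownames(intensity))) {
    if (nrow(intensity) > 0L)
      stop("intensity matrix needs formula rownames")
    rownames(intensity) <- character(0)
  }
  if (any(intensity < 0)) stop("negative intensities")
  if (!all(c("column", "sample_id") %in% names(meta)))
    stop("meta needs at least 'column' and 'sample_id'")
  if (nrow(meta) != ncol(intensity))
    stop("meta rows must match intensity columns")
  colnames(intensity) <- meta$column
  ann <- annotate_formulas(parse_formula(rownames(intensity)))
  rownames(ann) <- ann$formula
  structure(list(intensity = intensity, annotation = ann, meta = meta),
            class = "dom_crosstable")
}

#' @export
print.dom_crosstable <- function(x, ...) {
  cat(sprintf("<dom_crosstable> %d formulas x %d columns (%d samples)\n",
              nrow(x$intensity), ncol(x$intensity),
              length(unique(x$meta$sample_id))))
  lg <- attr(x, "removal_log")
  if (!is.null(lg) && nrow(lg))
    cat(sprintf("  reduction log: %d entries, %d rows removed in total\n",
                nrow(lg), sum(lg$n_removed)))
  invisible(x)
}

#' @export
dim.dom_crosstable <- function(x) dim(x$intensity)

# subset rows/columns, keeping annotation, meta and the removal log
ct_subset <- function(ct, rows = NULL, cols = NULL) {
  int <- ct$intensity
  if (!is.null(rows)) int <- int[rows, , drop = FALSE]
  meta <- ct$meta
  if (!is.null(cols)) {
    int <- int[, cols, drop = FALSE]
    meta <- meta[cols, , drop = FALSE]
  }
  out <- structure(list(intensity = int,
                        annotation = ct$annotation[rownames(int), , drop = FALSE],
                        meta = meta),
                   class = "dom_crosstable")
  attr(out, "removal_log") <- attr(ct, "removal_log")
  attr(out, "normalized") <- attr(ct, "normalized")
  out
}

# append one entry to the removal log carried by the cross table
log_removal <- function(ct, stage, rule, n_removed) {
  lg <- attr(ct, "removal_log")
  entry <- data.frame(stage = stage, rule = rule, n_removed = n_removed,
                      stringsAsFactors = FALSE)
  attr(ct, "removal_log") <- rbind(lg, entry)
  ct
}

#' Reduction removal log
#'
#' @param ct A [dom_crosstable()] that went through reduction stages.
#' @return data.frame with columns `stage`, `rule`, `n_removed` (one row per
#'   applied rule), or an empty data.frame.
#' @export
removal_log <- function(ct) {
  lg <- attr(ct, "removal_log")
  if (is.null(lg))
    lg <- data.frame(stage = character(0), rule = character(0),
                     n_removed = integer(0))
  lg
}

#' Combine per-measurement assignment tables into a cross table
#'
#' @param assigned_list List of assignment tables from [assign_peaklist()];
#'   names become column ids (defaults to `sample_id.replicate_id`).
#' @param groups Optional vector (recycled) giving the experimental group
#'   (e.g. Fe level) of each column.
#' @return A [dom_crosstable()] keyed by exact composition.
#' @export
build_crosstable <- function(assigned_list, groups = NA) {
  if (!length(assigned_list)) stop("no assignment tables supplied")
  ids <- names(assigned_list)
  samp <- vapply(assigned_list, function(a)
    attr(a, "sample_id") %||% "sample", "")
  repl <- vapply(assigned_list, function(a)
    attr(a, "replicate_id") %||% "1", "")
  if (is.null(ids)) ids <- paste(samp, repl, sep = ".")
  formulas <- sort(unique(unlist(lapply(assigned_list, `[[`, "formula"))))
  int <- matrix(0, nrow = length(formulas), ncol = length(assigned_list),
                dimnames = list(formulas, ids))
  for (j in seq_along(assigned_list)) {
    a <- assigned_list[[j]]
    # a peak list can in principle yield two peaks with one formula; sum them
    agg <- tapply(a$intensity, a$formula, sum)
    int[names(agg), j] <- agg
  }
  meta <- data.frame(column = ids, sample_id = samp, replicate_id = repl,
                     group = rep_len(groups, length(ids)),
                     stringsAsFactors = FALSE)
  dom_crosstable(int, meta)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
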