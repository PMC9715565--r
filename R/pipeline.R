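# Orchestration, configuration and file round-trips.

#' Pipeline run configuration
#'
#' Collects every tunable threshold of the workflow in one object. A config
#' snapshot accompanies every [run_pipeline()] result for provenance.
#'
#' @param seed Seed for the few stochastic steps (Monte-Carlo permutation
#'   p-values at very small n).
#' @param tol_ppm Assignment tolerance (ppm, strict).
#' @param match_ppm Coarse recalibration matching window (ppm).
#' @param mdl_noise_quantile Noise-population fraction for [estimate_mdl()].
#' @param blank_factor Blank comparison factor, see [blank_filter()].
#' @param smooth_factor,smooth_window Spectral smoothing parameters.
#' @param min_samples Minimum sample occurrence.
#' @param top_n Formulas kept per sample in the normalised dataset.
#' @param alpha,r_cutoff,cor_method Correlation screen parameters.
#' @param outlier_threshold Relative average-m/z deviation flagging a
#'   replicate as outlier.
#' @param isotope_floor_mult,isotope_ratio_window 13C verification
#'   parameters.
#' @param v_plume,v_control Endmember mixing volumes (mL).
#' @param ideg_weights Plume/control profile weights for the mixed
#'   degradation index.
#' @param stages Named logical list toggling `reduce`, `indices`, `mixing`,
#'   `ecology`.
#' @return Object of class `run_config`.
#' @export
run_config <- function(seed = 1L, tol_ppm = 0.5, match_ppm = 2,
                       mdl_noise_quantile = 0.1, blank_factor = 1,
                       smooth_factor = 2, smooth_window = 10L,
                       min_samples = 2L, top_n = 1000L, alpha = 0.05,
                       r_cutoff = 0.5, cor_method = "spearman",
                       outlier_threshold = 0.05, isotope_floor_mult = 20,
                       isotope_ratio_window = c(0.2, 5),
                       v_plume = 50, v_control = 450,
                       ideg_weights = c(1, 9),
                       stages = list(reduce = TRUE, indices = TRUE,
                                     mixing = TRUE, ecology = TRUE)) {
  cfg <- as.list(environment())
  class(cfg) <- "run_config"
  cfg
}

#' Read a pipeline configuration from a YAML file
#'
#' Keys not understood by [run_config()] are rejected.
#'
#' @param path YAML file.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  vals <- yaml::read_yaml(path)
  known <- names(formals(run_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown))
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
  do.call(run_config, vals)
}

#' Read a peak list from delimited text or mzML
#'
#' Delimited files need two numeric columns (m/z, intensity); comma, tab or
#' semicolon separated, header optional. `.mzML` files are read through mzR
#' (if installed) and flattened to centroid pairs. m/z values must be
#' strictly increasing and intensities positive.
#'
#' @param path Input file.
#' @param sample_id,replicate_id,is_blank Metadata for the [peaklist()];
#'   defaults derive the sample id from the file name.
#' @return A [peaklist()].
#' @export
read_peaklist <- function(path, sample_id = NULL, replicate_id = 1L,
                          is_blank = FALSE) {
  if (is.null(sample_id))
    sample_id <- sub("\\.[^.]*$", "", basename(path))
  if (grepl("\\.mzml$", path, ignore.case = TRUE)) {
    if (!requireNamespace("mzR", quietly = TRUE))
      stop("reading mzML requires the mzR package")
    h <- mzR::openMSfile(path)
    on.exit(mzR::close(h))
    pk <- mzR::peaks(h)
    if (is.list(pk)) pk <- do.call(rbind, pk)
    mz <- pk[, 1]; int <- pk[, 2]
  } else {
    first <- readLines(path, n = 1L)
    sep <- if (grepl("\t", first)) "\t" else if (grepl(";", first)) ";" else ","
    header <- !grepl("^[0-9.eE+,;\t-]+$", first)
    tab <- utils::read.table(path, sep = sep, header = header,
                             comment.char = "#", stringsAsFactors = FALSE)
    if (ncol(tab) < 2L || !is.numeric(tab[[1]]) || !is.numeric(tab[[2]]))
      stop("peak list '", path, "' needs two numeric columns (m/z, intensity)")
    mz <- tab[[1]]; int <- tab[[2]]
  }
  if (any(diff(mz) <= 0))
    stop("non-monotone m/z axis in '", path, "'")
  if (any(int < 0))
    stop("negative intensity in '", path, "'")
  keep <- int > 0
  peaklist(mz[keep], int[keep], sample_id = sample_id,
           replicate_id = replicate_id, is_blank = is_blank)
}

#' Write a peak list at full precision
#'
#' @param pl A [peaklist()].
#' @param path Output CSV; numeric values round-trip exactly.
#' @export
write_peaklist <- function(pl, path) {
  lines <- c("mz,intensity",
             paste(formatC(pl$mz, digits = 17, format = "g"),
                   formatC(pl$intensity, digits = 17, format = "g"),
                   sep = ","))
  writeLines(lines, path)
  invisible(path)
}

#' Write a cross table as delimited text
#'
#' Rows are formulas (canonical string, element counts and indices followed
#' by per-column intensities); column metadata is embedded in `#meta` header
#' lines so [read_crosstable()] restores the object losslessly.
#'
#' @param ct A [dom_crosstable()].
#' @param path Output CSV.
#' @export
write_crosstable <- function(ct, path) {
  meta <- ct$meta
  hdr <- vapply(seq_len(nrow(meta)), function(i)
    paste0("#meta,", paste(meta$column[i], meta$sample_id[i],
                           meta$replicate_id[i],
                           if ("group" %in% names(meta)) meta$group[i] else NA,
                           sep = ",")), "")
  ann <- ct$annotation
  num <- function(x) formatC(x, digits = 17, format = "g")
  body <- cbind(formula = ann$formula,
                as.data.frame(lapply(ann[, ELEMENTS], as.character)),
                neutral_mass = num(ann$neutral_mass),
                as.data.frame(apply(ct$intensity, 2L, num)))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  utils::write.table(body, con, sep = ",", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a cross table written by [write_crosstable()]
#'
#' @param path Input CSV.
#' @return A [dom_crosstable()]; intensities identical to what was written.
#' @export
read_crosstable <- function(path) {
  lines <- readLines(path)
  metal <- grep("^#meta,", lines, value = TRUE)
  meta <- do.call(rbind, lapply(strsplit(sub("^#meta,", "", metal), ","),
                                function(p) data.frame(column = p[1],
                                                       sample_id = p[2],
                                                       replicate_id = p[3],
                                                       group = p[4],
                                                       stringsAsFactors = FALSE)))
  tab <- read.csv(path, comment.char = "#", check.names = FALSE,
                  stringsAsFactors = FALSE)
  int_cols <- setdiff(names(tab), c("formula", ELEMENTS, "neutral_mass"))
  int <- as.matrix(tab[, int_cols, drop = FALSE])
  rownames(int) <- tab$formula
  dom_crosstable(int, meta)
}

#' Read a sample chemistry table
#'
#' @param path CSV with at least `sample`, `role`, `dfe` columns (see the
#'   file shipped under `extdata` for the full layout).
#' @return data.frame.
#' @export
read_chem <- function(path) {
  chem <- read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  need <- c("sample", "role", "dfe")
  if (!all(need %in% names(chem)))
    stop("chemistry table needs columns: ", paste(need, collapse = ", "))
  chem
}

#' Run the complete workflow
#'
#' Executes, in fixed order: per-measurement assignment (MDL,
#' recalibration, grid enumeration, series resolution, 13C verification),
#' cross-table construction, the reduction cascade, quality-control
#' exclusion, per-sample and per-section summaries, endmember mixing
#' reconstruction, and the ordination/correlation screens. Each stage logs
#' its row counts.
#'
#' @param sim A `dom_simulation` from [simulate_experiment()], or a
#'   directory written by [write_synthetic_dataset()].
#' @param config A [run_config()].
#' @return Object of class `dom_pipeline_result`: list with `config`,
#'   `crosstable` (reduced, merged), `sections`, `summaries`,
#'   `section_summaries`, `qc`, `mixing`, `ecology`, `log` and the raw
#'   `assigned` tables.
#' @export
run_pipeline <- function(sim, config = run_config()) {
  if (is.character(sim)) sim <- load_synthetic_dataset(sim)
  stages <- config$stages
  log <- list()
  note <- function(stage, detail, n_in, n_out)
    log[[length(log) + 1L]] <<- data.frame(stage = stage, detail = detail,
                                           rows_in = n_in, rows_out = n_out,
                                           stringsAsFactors = FALSE)

  # --- assignment -----------------------------------------------------
  assigned <- list()
  groups <- character(0)
  chem <- sim$chemistry
  for (id in names(sim$peaklists)) {
    reps <- sim$peaklists[[id]]
    for (r in seq_along(reps)) {
      a <- assign_peaklist(reps[[r]], reference = sim$calibrants,
                           tol_ppm = config$tol_ppm,
                           floor_mult = config$isotope_floor_mult,
                           ratio_window = config$isotope_ratio_window)
      assigned[[paste0(id, ".m", r)]] <- a
      note("assign", paste0(id, ".m", r), nrow(reps[[r]]), nrow(a))
      row <- chem[chem$sample == id, ]
      groups <- c(groups,
                  if (nrow(row) && row$role[1] == "incubation")
                    sprintf("fe_%g", row$fe_nominal[1])
                  else if (nrow(row)) row$role[1] else id)
    }
  }
  blanks_assigned <- lapply(names(sim$blanks), function(b) {
    assign_peaklist(sim$blanks[[b]], reference = sim$calibrants,
                    tol_ppm = config$tol_ppm,
                    floor_mult = config$isotope_floor_mult,
                    ratio_window = config$isotope_ratio_window)
  })
  names(blanks_assigned) <- names(sim$blanks)

  ct <- build_crosstable(assigned, groups = groups)
  blank_ct <- build_crosstable(blanks_assigned, groups = "blank")
  note("crosstable", "formulas x measurements", nrow(ct$intensity),
       nrow(ct$intensity))
  if (!isTRUE(stages$reduce))
    return(structure(list(config = config, assigned = assigned,
                          crosstable = ct, log = do.call(rbind, log)),
                     class = "dom_pipeline_result"))

  # --- reduction ------------------------------------------------------
  n0 <- nrow(ct$intensity)
  red <- suppressWarnings(reduce_crosstable(
    ct, blanks = blank_ct, blank_factor = config$blank_factor,
    smooth_factor = config$smooth_factor,
    smooth_window = config$smooth_window, min_samples = config$min_samples))
  note("reduce", "cascade", n0, nrow(red$intensity))

  # --- quality control ------------------------------------------------
  summ_all <- suppressWarnings(dom_summary(red))
  qc_in <- data.frame(sample = summ_all$sample,
                      group = red$meta$group[match(summ_all$sample,
                                                   red$meta$sample_id)],
                      mz = summ_all$mz)
  qc <- qc_flags(chem, qc_in, outlier_threshold = config$outlier_threshold)
  excluded <- qc$sample[qc$contaminated | qc$outlier]
  keep_cols <- !(red$meta$sample_id %in% excluded)
  red_kept <- ct_subset(red, cols = keep_cols)
  note("qc", paste("excluded:", paste(excluded, collapse = ", ")),
       ncol(red$intensity), ncol(red_kept$intensity))

  out <- list(config = config, assigned = assigned, crosstable = red,
              qc = qc, summaries = summ_all)
  if (isTRUE(stages$indices)) {
    inc <- grepl("^fe_", red_kept$meta$group) | red_kept$meta$group == "control"
    sections <- section_intersect(ct_subset(red_kept, cols = inc))
    out$sections <- sections
    out$section_summaries <- suppressWarnings(dom_summary(sections))
    note("indices", "section summaries", ncol(sections$intensity),
         nrow(out$section_summaries))
  }

  # --- mixing ---------------------------------------------------------
  if (isTRUE(stages$mixing) && "plume" %in% red$meta$sample_id &&
      "control" %in% red_kept$meta$group) {
    plume_chem <- chem[chem$role == "plume", ]
    control_chem <- chem[chem$role == "control", ]
    plume_col <- red$intensity[, red$meta$sample_id == "plume", drop = TRUE]
    plume_profile <- plume_col[plume_col > 0]
    ctrl_section <- out$sections
    cc <- which(colnames(ctrl_section$intensity) == "control")
    ctrl_profile <- ctrl_section$intensity[, cc]
    ctrl_profile <- ctrl_profile[ctrl_profile > 0]
    plume_summ <- summ_all[summ_all$sample == "plume",
                           c("mz", "h_c", "o_c", "aimod", "dbe", "nosc",
                             "df_c", "df_hc", "df_nosc")]
    ctrl_summ <- out$section_summaries[
      out$section_summaries$sample == "control",
      c("mz", "h_c", "o_c", "aimod", "dbe", "nosc", "df_c", "df_hc",
        "df_nosc")]
    out$mixing <- reconstruct_initial_solution(
      plume_chem, control_chem,
      v_plume = config$v_plume, v_control = config$v_control,
      plume_summary = plume_summ, control_summary = ctrl_summ,
      plume_profile = plume_profile, control_profile = ctrl_profile,
      ideg_weights = config$ideg_weights)
    note("mixing", "initial solution reconstructed", 1, 1)
  }

  # --- ecology --------------------------------------------------------
  if (isTRUE(stages$ecology) && !is.null(sim$covariates)) {
    inc <- grepl("^fe_", red_kept$meta$group)
    sub <- ct_subset(red_kept, cols = inc)
    norm <- top_n_normalize(sub, n = config$top_n)
    d <- bray_curtis(norm)
    cov <- sim$covariates
    fe <- setNames(cov$fe, cov$sample)
    covn <- cov[, setdiff(names(cov), "fe")]
    hits <- correlate_formulae(norm, covn, fe = fe,
                               method = config$cor_method,
                               alpha = config$alpha,
                               r_cutoff = config$r_cutoff)
    out$ecology <- list(dissimilarity = d, pcoa = dom_pcoa(d), hits = hits,
                        highlighted = highlight_unconfounded(hits))
    note("ecology", "correlation screen", nrow(norm$intensity), nrow(hits))
  }
  out$log <- do.call(rbind, log)
  class(out) <- "dom_pipeline_result"
  out
}

#' @export
print.dom_pipeline_result <- function(x, ...) {
  cat("<dom_pipeline_result>\n")
  cat(sprintf("  reduced cross table: %d formulas x %d columns\n",
              nrow(x$crosstable$intensity), ncol(x$crosstable$intensity)))
  if (!is.null(x$section_summaries))
    cat(sprintf("  sections: %s\n",
                paste(x$section_summaries$sample, collapse = ", ")))
  if (!is.null(x$ecology))
    cat(sprintf("  correlation hits: %d (%d unconfounded)\n",
                nrow(x$ecology$hits), nrow(x$ecology$highlighted)))
  invisible(x)
}

# reload a dataset written by write_synthetic_dataset()
load_synthetic_dataset <- function(dir) {
  pk_files <- list.files(file.path(dir, "peaklists"), full.names = TRUE)
  ids <- sub("_m[0-9]+\\.csv$", "", basename(pk_files))
  peaklists <- list()
  for (i in seq_along(pk_files)) {
    r <- as.integer(sub("^.*_m([0-9]+)\\.csv$", "\\1", pk_files[i]))
    peaklists[[ids[i]]] <- c(peaklists[[ids[i]]],
                             list(read_peaklist(pk_files[i], sample_id = ids[i],
                                                replicate_id = r)))
  }
  blanks <- list()
  for (f in list.files(file.path(dir, "blanks"), full.names = TRUE)) {
    id <- sub("\\.csv$", "", basename(f))
    blanks[[id]] <- read_peaklist(f, sample_id = id, is_blank = TRUE)
  }
  list(peaklists = peaklists, blanks = blanks,
       chemistry = read_chem(file.path(dir, "chemistry.csv")),
       covariates = read.csv(file.path(dir, "covariates.csv"),
                             stringsAsFactors = FALSE),
       calibrants = readLines(file.path(dir, "calibrants.txt")))
}
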