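# Shared fixtures, generated once per test run.

# small synthetic experiment for fast structural tests
small_sim <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- simulate_experiment(synthetic_config(seed = 42,
                                                     n_formulas = 500,
                                                     n_noise_peaks = 80))
    cache
  }
})

# pipeline result for the small experiment
small_run <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- suppressWarnings(run_pipeline(small_sim()))
    cache
  }
})

# full default-scale experiment + pipeline run (acceptance-grade conditions)
full_sim <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- simulate_experiment(synthetic_config(seed = 1))
    cache
  }
})

full_run <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- suppressWarnings(run_pipeline(full_sim()))
    cache
  }
})

# hand-built cross table: intensity matrix + minimal metadata
make_ct <- function(formulas, intensity, sample_ids = NULL, groups = NA) {
  intensity <- as.matrix(intensity)
  rownames(intensity) <- formulas
  if (is.null(sample_ids)) sample_ids <- paste0("s", seq_len(ncol(intensity)))
  colnames(intensity) <- make.unique(sample_ids)
  meta <- data.frame(column = colnames(intensity), sample_id = sample_ids,
                     replicate_id = as.character(seq_len(ncol(intensity))),
                     group = rep_len(groups, ncol(intensity)),
                     stringsAsFactors = FALSE)
  dom_crosstable(intensity, meta)
}

# published endmember tables shipped with the package
endmember_chem <- function() {
  read_chem(system.file("extdata", "incubation_chemistry.csv",
                        package = "ferrodom"))
}

endmember_dom <- function() {
  read.csv(system.file("extdata", "incubation_dom_summaries.csv",
                       package = "ferrodom"),
           comment.char = "#", stringsAsFactors = FALSE)
}
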