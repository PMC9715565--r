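# Data-reduction cascade and quality control.

test_that("elemental filters enforce the composition restrictions", {
  ct <- make_ct(c("C5H10O6", "C10H23O3", "C15H14O6", "C10H12N6O6", "C9H12N6O7"),
                matrix(1, 5, 2))
  # C5H10O6 violates C >= O; C10H23O3 violates H <= 2C+2 (23 > 22)
  out <- elemental_filters(ct)
  expect_identical(rownames(out$intensity), c("C15H14O6", "C10H12N6O6",
                                              "C9H12N6O7"))
  lg <- removal_log(out)
  expect_identical(sum(lg$n_removed), 2L)
  expect_identical(lg$n_removed[lg$rule == "C >= O"], 1L)
  expect_identical(lg$n_removed[lg$rule == "H <= 2C + 2"], 1L)
})

test_that("blank filter deletes formulas not exceeding the blank intensity", {
  ct <- make_ct(c("C10H12O4", "C12H16O4", "C14H20O4"),
                matrix(c(100, 500, 300), 3, 1))
  blanks <- c(C10H12O4 = 500, C12H16O4 = 100)
  out <- blank_filter(ct, blanks)
  expect_false("C10H12O4" %in% rownames(out$intensity))  # 100 <= 500
  expect_true("C12H16O4" %in% rownames(out$intensity))   # 500 > 100
  expect_true("C14H20O4" %in% rownames(out$intensity))   # absent from blanks
})

test_that("spectral smoothing removes spikes but not smooth envelopes", {
  f <- format_formula(formula_table(C = 10:40, H = 12, O = 4))
  mass <- monoisotopic_mass(formula_table(C = 10:40, H = 12, O = 4))
  env <- exp(-((mass - mean(mass)) / 150)^2) * 1e6   # smooth Gaussian
  ct <- make_ct(f, matrix(env, ncol = 1))
  out <- spectral_smoothing_filter(ct)
  expect_identical(nrow(out$intensity), length(f))
  # plant a 10x spike in the middle
  spiked <- env; spiked[15] <- 10 * max(env)
  ct2 <- make_ct(f, matrix(spiked, ncol = 1))
  out2 <- spectral_smoothing_filter(ct2)
  expect_false(f[15] %in% rownames(out2$intensity))
  expect_identical(nrow(out2$intensity), length(f) - 1L)
  # boundary peak level with its neighbours survives
  flat <- rep(1e6, length(f))
  out3 <- spectral_smoothing_filter(make_ct(f, matrix(flat, ncol = 1)))
  expect_identical(nrow(out3$intensity), length(f))
})

test_that("replicate merging intersects formulas and averages intensities", {
  ct <- make_ct(c("C10H12O4", "C12H16O4"),
                cbind(c(100, 0), c(300, 200)),
                sample_ids = c("s1", "s1"))
  out <- merge_replicates(ct)
  expect_identical(rownames(out$intensity), "C10H12O4")
  expect_equal(unname(out$intensity[1, 1]), 200)
  # single measurement passes through with a warning
  ct2 <- make_ct("C10H12O4", matrix(50, 1, 1), sample_ids = "solo")
  expect_warning(out2 <- merge_replicates(ct2), "unmerged")
  expect_equal(unname(out2$intensity[1, 1]), 50)
  # identical replicates: identity
  ct3 <- make_ct(c("C10H12O4", "C12H16O4"), cbind(c(1, 2), c(1, 2)),
                 sample_ids = c("a", "a"))
  out3 <- merge_replicates(ct3)
  expect_equal(unname(out3$intensity[, 1]), c(1, 2))
})

test_that("minimum sample occurrence removes near-unique formulas", {
  ct <- make_ct(c("C10H12O4", "C12H16O4"), cbind(c(1, 1), c(0, 1), c(0, 1)))
  out <- min_sample_filter(ct)
  expect_identical(rownames(out$intensity), "C12H16O4")
  empty <- min_sample_filter(make_ct(character(0), matrix(0, 0, 2)))
  expect_identical(nrow(empty$intensity), 0L)
})

test_that("top-n normalisation keeps the strongest formulas and unit column sums", {
  set.seed(8)
  n <- 1500
  ft <- formula_table(C = sample(5:50, n, TRUE), H = sample(seq(2, 60, 2), n, TRUE),
                      O = sample(1:5, n, TRUE))
  ft <- ft[!duplicated(format_formula(ft)), ]
  f <- format_formula(ft)
  ct <- make_ct(f, matrix(rlnorm(length(f), 10, 1), ncol = 1))
  out <- top_n_normalize(ct, n = 1000)
  expect_identical(sum(out$intensity[, 1] > 0), 1000L)
  expect_equal(sum(out$intensity[, 1]), 1, tolerance = 1e-9)
  # tie at the cut rank: the lower-mass formula is kept
  f3 <- c("C10H12O4", "C12H16O4", "C8H8O2")
  ct2 <- make_ct(f3, matrix(c(5, 1, 1), ncol = 1))
  out2 <- top_n_normalize(ct2, n = 2)
  kept <- rownames(out2$intensity)[out2$intensity[, 1] > 0]
  expect_true("C8H8O2" %in% kept)     # lighter of the two tied formulas
  expect_false("C12H16O4" %in% kept)
})

test_that("section intersection requires presence in all replicates", {
  ct <- make_ct(c("C10H12O4", "C12H16O4"),
                cbind(c(1, 1), c(1, 0), c(1, 3)),
                sample_ids = c("r1", "r2", "r3"), groups = "g1")
  out <- section_intersect(ct)
  expect_identical(rownames(out$intensity), "C10H12O4")
  expect_equal(unname(out$intensity[1, 1]), 1)
  # singleton group: identity
  ct1 <- make_ct("C10H12O4", matrix(7, 1, 1), sample_ids = "r1", groups = "g")
  out1 <- section_intersect(ct1)
  expect_equal(unname(out1$intensity[1, 1]), 7)
  # disjoint replicates: empty section
  ct2 <- make_ct(c("C10H12O4", "C12H16O4"), cbind(c(1, 0), c(0, 1)),
                 sample_ids = c("r1", "r2"), groups = "g")
  expect_identical(nrow(section_intersect(ct2)$intensity), 0L)
})

test_that("quality control flags contaminated extracts and replicate outliers", {
  chem <- data.frame(sample = c("a", "b"), tdn = c(4.2, 2.9),
                     spe_tdn = c(1.2, 6.7))
  qc <- qc_flags(chem)
  expect_identical(qc$contaminated, c(FALSE, TRUE))
  summ <- data.frame(sample = c("r1", "r2", "r3"), group = "g",
                     mz = c(402, 355, 361))
  chem2 <- data.frame(sample = c("r1", "r2", "r3"), tdn = 1, spe_tdn = 0.1)
  qc2 <- qc_flags(chem2, summ)
  expect_identical(qc2$outlier, c(TRUE, FALSE, FALSE))
  # equal replicates: nothing flagged
  summ$mz <- 380
  expect_false(any(qc_flags(chem2, summ)$outlier))
})

test_that("the cascade is idempotent and accounts every removal to one rule", {
  # planted violations: one per elemental rule, a blank contaminant, a known
  # contaminant, a spike and a singleton formula
  good <- format_formula(formula_table(C = 10:29, H = 14, O = 5))
  bad <- c("C5H10O6",       # C >= O
           "C10H23O3",      # H <= 2C+2
           "C12H26O4S")     # known contaminant list
  f <- c(good, bad, "C9H10O4")
  set.seed(9)
  m <- matrix(rep(1e6 * exp(rnorm(length(f), 0, 0.1)), 4), ncol = 4)
  m[f == "C9H10O4", 2:4] <- 0                      # singleton (one sample)
  m[f == good[10], ] <- m[f == good[10], ] * 50    # spike
  ct <- make_ct(f, m, sample_ids = c("s1", "s1", "s2", "s2"))
  blanks <- setNames(2e6, good[5])                 # blank above sample
  out <- suppressWarnings(
    reduce_crosstable(ct, blanks = blanks))
  lg <- removal_log(out)
  expect_identical(lg$n_removed[lg$rule == "C >= O"], 1L)
  expect_identical(lg$n_removed[lg$rule == "H <= 2C + 2"], 1L)
  expect_identical(lg$n_removed[lg$rule == "known contaminant list"], 1L)
  expect_identical(lg$n_removed[lg$rule == "rows fully blanked"], 1L)
  expect_false(good[5] %in% rownames(out$intensity))
  expect_false(good[10] %in% rownames(out$intensity))
  expect_false("C9H10O4" %in% rownames(out$intensity))
  # idempotence: a second pass removes nothing and changes no value
  out2 <- suppressWarnings(
    reduce_crosstable(out, blanks = blanks, merge = FALSE))
  expect_equal(out2$intensity, out$intensity)
  lg2 <- removal_log(out2)
  new_rows <- lg2[-seq_len(nrow(lg)), ]
  expect_identical(sum(new_rows$n_removed), 0L)
})

test_that("reduction row counts are non-increasing through the cascade", {
  sim <- small_sim()
  ids <- names(sim$peaklists)[5:6]
  assigned <- list()
  for (id in ids)
    for (r in 1:2)
      assigned[[paste0(id, ".m", r)]] <-
        assign_peaklist(sim$peaklists[[id]][[r]], reference = sim$calibrants)
  ct <- build_crosstable(assigned)
  n0 <- nrow(ct$intensity)
  out <- suppressWarnings(reduce_crosstable(ct))
  lg <- removal_log(out)
  expect_lte(nrow(out$intensity), n0)
  # removals in the log match the observed row loss for row-wise stages
  expect_true(all(lg$n_removed >= 0))
})
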