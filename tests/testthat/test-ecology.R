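# Dissimilarity, ordination and correlation screens.

test_that("Bray-Curtis dissimilarity matches hand sums", {
  ct <- make_ct(c("C10H12O4", "C12H16O4", "C14H20O4"),
                cbind(a = c(1, 1, 0), b = c(0, 1, 1), c = c(1, 1, 0)),
                sample_ids = c("a", "b", "c"))
  d <- bray_curtis(ct)
  expect_equal(unname(d["a", "b"]), 0.5)
  expect_equal(unname(d["a", "c"]), 0)
  expect_true(all(diag(d) == 0))
  expect_equal(d, t(d))
  # disjoint supports
  ct2 <- make_ct(c("C10H12O4", "C12H16O4"), cbind(c(1, 0), c(0, 1)),
                 sample_ids = c("a", "b"))
  expect_equal(unname(bray_curtis(ct2)["a", "b"]), 1)
})

test_that("principal coordinates reproduce known geometries", {
  # three equidistant samples: two equal positive eigenvalues
  d3 <- matrix(1, 3, 3); diag(d3) <- 0
  p <- dom_pcoa(d3)
  expect_identical(ncol(p$coordinates), 2L)
  expect_equal(p$eigenvalues[1], p$eigenvalues[2], tolerance = 1e-9)
  # points on a line: one positive axis, distances recovered exactly
  x <- c(0, 1, 3, 7)
  dl <- as.matrix(dist(x))
  pl <- dom_pcoa(dl)
  expect_identical(ncol(pl$coordinates), 1L)
  rec <- as.matrix(dist(pl$coordinates[, 1]))
  expect_equal(rec, dl, tolerance = 1e-8, ignore_attr = TRUE)
  # two samples: separation equals the dissimilarity
  d2 <- matrix(c(0, 0.4, 0.4, 0), 2)
  p2 <- dom_pcoa(d2)
  expect_equal(abs(diff(p2$coordinates[, 1])), 0.4, tolerance = 1e-9)
  expect_error(dom_pcoa(matrix(c(0, 1, 2, 0), 2)), "symmetric")
})

test_that("correlation screens recover perfect monotone relationships", {
  set.seed(14)
  n <- 12
  cov <- data.frame(sample = paste0("s", 1:n), g1 = runif(n))
  f1 <- cov$g1 * 2                       # proportional
  f2 <- exp(-3 * cov$g1)                 # reversed, monotone
  f3 <- rep(0.5, n)                      # constant: skipped
  int <- rbind(C10H12O4 = f1, C12H16O4 = f2, C14H20O4 = f3)
  ct <- make_ct(rownames(int), int, sample_ids = cov$sample)
  hits <- correlate_formulae(ct, cov, method = "spearman")
  expect_equal(hits$r[hits$formula == "C10H12O4"], 1)
  expect_equal(hits$r[hits$formula == "C12H16O4"], -1)
  expect_identical(attr(hits, "skipped"), "C14H20O4")
})

test_that("Spearman statistics are invariant under monotone transforms", {
  set.seed(15)
  x <- rnorm(15); y <- rnorm(15)
  r1 <- ferrodom:::spearman_screen(x, y)
  r2 <- ferrodom:::spearman_screen(exp(x), y)
  r3 <- ferrodom:::spearman_screen(x, y^3 + 5 * y)
  expect_equal(r1, r2)
  expect_equal(r1, r3)
})

test_that("small-sample Spearman p-values agree with the exact reference", {
  set.seed(16)
  for (i in 1:5) {
    x <- rnorm(7); y <- rnorm(7)
    mine <- ferrodom:::spearman_screen(x, y)
    ref <- cor.test(x, y, method = "spearman", exact = TRUE)
    expect_equal(unname(mine["r"]), unname(ref$estimate), tolerance = 1e-12)
    expect_equal(unname(mine["p"]), ref$p.value, tolerance = 1e-9)
  }
})

test_that("iron-confounded hits are annotated and filterable", {
  set.seed(17)
  n <- 14
  fe <- 10^seq(0, 4, length.out = n)
  cov <- data.frame(sample = paste0("s", 1:n),
                    gFe = log10(fe + 1) / 5 + rnorm(n, 0, 0.01),
                    gInd = runif(n))
  f_fe <- log10(fe + 1) + rnorm(n, 0, 0.05)    # tracks iron
  f_ind <- cov$gInd * 3 + rnorm(n, 0, 0.01)    # tracks the free covariate
  ct <- make_ct(c("C10H12O4", "C12H16O4"), rbind(f_fe, f_ind),
                sample_ids = cov$sample)
  hits <- correlate_formulae(ct, cov, fe = setNames(fe, cov$sample))
  fe_hit <- hits[hits$formula == "C10H12O4" & hits$covariate == "gFe", ]
  ind_hit <- hits[hits$formula == "C12H16O4" & hits$covariate == "gInd", ]
  expect_true(fe_hit$fe_confounded)
  expect_false(ind_hit$fe_confounded)
  kept <- highlight_unconfounded(hits)
  expect_true(all(!kept$fe_confounded))
  expect_true("C12H16O4" %in% kept$formula)
  expect_identical(nrow(highlight_unconfounded(hits[hits$fe_confounded, ])), 0L)
})

test_that("planted group-linked formulas are recovered in the experiment screen", {
  sim <- small_sim()
  run <- small_run()
  hits <- run$ecology$hits
  lib <- sim$library
  planted <- lib$formula[!is.na(lib$linked_group)]
  groups <- lib$linked_group[!is.na(lib$linked_group)]
  # only formulas that survived assignment and reduction in most samples can
  # carry their planted signal (full-scale recovery is asserted in the
  # acceptance suite)
  red <- run$crosstable
  inc <- grepl("^fe_", red$meta$group)
  detected <- planted %in% rownames(red$intensity) &
    vapply(planted, function(f)
      f %in% rownames(red$intensity) &&
        sum(red$intensity[f, inc] > 0) >= 15, logical(1))
  expect_gt(sum(detected), 0)
  found <- mapply(function(f, g)
    any(hits$formula == f & hits$covariate == g & hits$r > 0),
    planted[detected], groups[detected])
  expect_true(all(found))
})
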