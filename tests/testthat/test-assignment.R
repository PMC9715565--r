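# Formula assignment: detection limit, recalibration, candidate search,
# series resolution, isotopologue verification.

test_that("method detection limit is mean + 2 SD of the noise population", {
  # lowest decile exactly {1..100}: 1000 peaks, the rest at high intensity
  mz <- 100 + seq_len(1000) * 0.37
  int <- c(1:100, runif(900, 1e6, 2e6))
  pl <- peaklist(mz, int)
  expect_equal(estimate_mdl(pl), mean(1:100) + 2 * sd(1:100))
  # degenerate: all noise equal
  pl2 <- peaklist(mz[1:100], c(rep(5, 10), runif(90, 1e6, 2e6)))
  expect_equal(estimate_mdl(pl2), 5)
  expect_error(estimate_mdl(peaklist(numeric(0), numeric(0))))
  expect_warning(thr <- estimate_mdl(peaklist(1:5 + 100, rep(1, 5))),
                 "fewer than 20")
  expect_identical(thr, 0)
})

test_that("recalibration removes constant offsets and smooth drift", {
  refs <- format_formula(formula_table(C = 10:60, H = 12:62, O = 5))
  ref_mz <- mz_deprotonated(refs)
  # constant +0.4 ppm offset
  pl <- peaklist(ref_mz * (1 + 0.4e-6), rep(1e6, length(ref_mz)))
  cal <- recalibrate(pl, refs)
  err <- (cal$mz - ref_mz) / ref_mz * 1e6
  expect_lt(max(abs(err)), 0.02)
  # linear drift 0 -> 0.4 ppm across the mass axis
  drift <- 0.4 * (ref_mz - min(ref_mz)) / diff(range(ref_mz))
  pl2 <- peaklist(ref_mz * (1 + drift * 1e-6), rep(1e6, length(ref_mz)))
  cal2 <- recalibrate(pl2, refs)
  err2 <- (cal2$mz - ref_mz) / ref_mz * 1e6
  expect_lt(max(abs(err2)), 0.1)
  # already calibrated: idempotent within 1e-4 ppm
  cal3 <- recalibrate(cal2, refs)
  expect_lt(max(abs(cal3$mz - cal2$mz) / cal2$mz * 1e6), 1e-4)
  # too few matches: unchanged with warning
  expect_warning(same <- recalibrate(pl, refs[1:3]), "fewer than 5")
  expect_equal(same$mz, pl$mz)
})

test_that("recalibration never degrades the median reference error", {
  set.seed(6)
  refs <- format_formula(formula_table(C = 8:58, H = 10:60, O = 4))
  ref_mz <- mz_deprotonated(refs)
  for (i in 1:10) {
    drift <- runif(1, -0.3, 0.3) * sin(ref_mz / runif(1, 50, 400)) +
      rnorm(length(ref_mz), 0, 0.1)
    pl <- peaklist(ref_mz * (1 + drift * 1e-6), rep(1e6, length(ref_mz)))
    cal <- recalibrate(pl, refs)
    rc <- attr(cal, "recalibration")
    expect_lte(rc$median_abs_after, rc$median_abs_before)
  }
})

test_that("candidate enumeration finds known formulas and rejects degenerate masses", {
  cand <- enumerate_candidates(monoisotopic_mass("C15H14O6"))
  expect_true("C15H14O6" %in% cand$formula)
  expect_identical(nrow(enumerate_candidates(12.0)), 0L)
  expect_true(all(abs(cand$error_ppm) < 0.5))
})

test_that("candidate enumeration is exactly equivalent to the brute-force grid oracle", {
  g <- brute_grid()
  ok <- oracle_heteroatoms_ok(g$N, g$S, g$P)
  set.seed(7)
  masses <- g$mass[sample(which(ok & g$mass < 400), 40)]
  for (m in masses) {
    fast <- sort(enumerate_candidates(m)$formula)
    expect_identical(fast, oracle_candidates(m))
  }
})

test_that("heteroatom prohibition matches the banned-combination list", {
  expect_false(allowed_heteroatoms(formula_table(C = 10, H = 15, N = 1, O = 5,
                                                 S = 1, P = 1)))
  expect_true(allowed_heteroatoms(formula_table(C = 10, H = 14, N = 4, O = 5)))
  expect_false(allowed_heteroatoms(formula_table(C = 10, H = 15, N = 2, O = 5,
                                                 S = 1)))
  # exhaustive agreement with the literal list over the whole block grid
  blocks <- expand.grid(N = 0:6, S = 0:2, P = 0:1)
  got <- allowed_heteroatoms(formula_table(C = 10, H = 12, N = blocks$N,
                                           O = 6, S = blocks$S, P = blocks$P))
  expect_identical(got, oracle_heteroatoms_ok(blocks$N, blocks$S, blocks$P))
  # Cl and Fe never disqualify
  expect_true(all(allowed_heteroatoms(formula_table(C = 10, H = 12, O = 6,
                                                    Cl = 0:2, Fe = 2:0))))
})

test_that("series resolution prefers homologous-series members and breaks ties by error", {
  # a 5-member CH2 ladder of unique-candidate peaks, then one ambiguous peak
  ladder <- formula_table(C = 10:14, H = 14 + 2 * (0:4), O = 4)
  cand <- data.frame(peak = 1:5, ladder,
                     neutral_mass = monoisotopic_mass(ladder),
                     error_ppm = 0.05, formula = format_formula(ladder))
  ext <- formula_table(C = 15, H = 24, O = 4)          # extends the ladder
  rival <- formula_table(C = 11, H = 8, N = 2, O = 7)  # unrelated
  amb <- data.frame(peak = 6L, rbind(ext, rival),
                    neutral_mass = monoisotopic_mass(rbind(ext, rival)),
                    error_ppm = c(0.30, 0.05),
                    formula = format_formula(rbind(ext, rival)))
  res <- resolve_by_series(rbind(cand, amb))
  expect_identical(nrow(res), 6L)
  expect_identical(res$formula[res$peak == 6L], format_formula(ext))
  expect_gte(res$series_score[res$peak == 6L], 1L)
  # equal series support: smaller |error| wins
  a <- formula_table(C = 20, H = 20, O = 5)
  b <- formula_table(C = 19, H = 16, N = 2, O = 5)
  tie <- data.frame(peak = 1L, rbind(a, b),
                    neutral_mass = monoisotopic_mass(rbind(a, b)),
                    error_ppm = c(0.3, 0.1), formula = format_formula(rbind(a, b)))
  res2 <- resolve_by_series(tie)
  expect_identical(res2$formula, format_formula(b))
  # single candidate chosen regardless of series
  single <- tie[1, ]
  expect_identical(resolve_by_series(single)$formula, single$formula)
})

test_that("13C verification keeps correct satellites, drops missing ones, skips weak peaks", {
  f <- formula_table(C = 20, H = 24, O = 8)
  mzv <- mz_deprotonated(f)
  mdl <- 1e4
  # peak with a correct satellite
  pl <- peaklist(c(mzv, mzv + 1.0033548), c(1e6, 0.011 * 20 * 1e6))
  assigned <- data.frame(mz = mzv, intensity = 1e6, f,
                         neutral_mass = monoisotopic_mass(f), error_ppm = 0,
                         formula = format_formula(f), series_score = 0L)
  out <- verify_isotopes(assigned, pl, mdl)
  expect_identical(nrow(out), 1L)
  expect_true(out$isotope_verified)
  # satellite absent for a strong peak: dropped
  pl2 <- peaklist(mzv, 1e6)
  out2 <- verify_isotopes(assigned, pl2, mdl)
  expect_identical(nrow(out2), 0L)
  # below the floor: retained untested
  weak <- assigned; weak$intensity <- 10 * mdl
  out3 <- verify_isotopes(weak, pl2, mdl)
  expect_identical(nrow(out3), 1L)
  expect_true(is.na(out3$isotope_verified))
})

# grid-bounds check mirroring the documented assignment grid
within_grid_test <- function(a) {
  a$C >= 1 & a$C <= 100 & a$H >= 1 & a$H <= 200 & a$O >= 1 & a$O <= 100 &
    a$N <= 6 & a$S <= 2 & a$P <= 1 & a$Cl <= 2 & a$Fe <= 2
}

test_that("assignments never violate the tolerance, the grid, or the prohibitions", {
  sim <- small_sim()
  ids <- names(sim$peaklists)[c(1, 5, 20)]
  for (id in ids) {
    a <- assign_peaklist(sim$peaklists[[id]][[1]], reference = sim$calibrants)
    expect_true(all(abs(a$error_ppm) < 0.5))
    expect_true(all(within_grid_test(a)))
    expect_true(all(allowed_heteroatoms(a)))
  }
})

test_that("isotopologue peaks are recognised by the parent-satellite pattern", {
  f <- formula_table(C = 15, H = 20, O = 6)
  mzv <- mz_deprotonated(f)
  pl <- peaklist(c(mzv, mzv + 1.0033548, mzv + 3), c(1e6, 1.6e5, 5e5))
  expect_identical(flag_isotopologues(pl), c(FALSE, TRUE, FALSE))
})
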