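# Ground-truth generator: determinism, constraints, coagulation behaviour.

test_that("identical seeds give byte-identical simulations", {
  cfg <- synthetic_config(seed = 21, n_formulas = 200, n_noise_peaks = 30)
  s1 <- simulate_experiment(cfg)
  s2 <- simulate_experiment(cfg)
  expect_identical(s1$library, s2$library)
  expect_identical(s1$chemistry, s2$chemistry)
  expect_identical(s1$covariates, s2$covariates)
  expect_identical(s1$peaklists, s2$peaklists)
})

test_that("the library respects every composition constraint and contains the planted sets", {
  lib <- small_sim()$library
  expect_true(all(allowed_heteroatoms(lib)))
  expect_true(all(lib$C >= lib$O))
  expect_true(all(lib$O > 2 * lib$P + lib$S))
  expect_true(all(lib$H <= 2 * lib$C + 2))
  expect_true(all(lib$N <= 6 & lib$S <= 2 & lib$P <= 1))
  expect_true(all(chemically_plausible(lib[, c("C", "H", "N", "O", "S",
                                               "P", "Cl", "Fe")])))
  expect_true(all(lib$mz >= 50 & lib$mz <= 1000))
  idx <- ideg_formulas()
  expect_true(all(c(idx$neg, idx$pos) %in% lib$formula))
  expect_true(all(c("C20H23FeN3O2", "C24H33FeN3O4", "C22H38FeO7S",
                    "C17H30FeN6O8") %in% lib$formula))
  expect_true(sum(lib$is_blank_contaminant) >= 10)
  expect_true(any(lib$formula %in% default_contaminants()))
})

test_that("zero coagulation strength makes retention independent of iron", {
  cfg <- synthetic_config(seed = 22, n_formulas = 400, n_noise_peaks = 20,
                          coagulation_strength = c(mz = 0, o_c = 0,
                                                   inv_hc = 0, nosc = 0),
                          global_removal = 0, fe_formula_removal = 0)
  lib <- build_library(cfg)
  set.seed(22)
  lo <- simulate_sample(lib, 0, cfg, "a")
  hi <- simulate_sample(lib, 10000, cfg, "b")
  expect_equal(nrow(lo$truth), nrow(hi$truth), tolerance = 0.08)
})

test_that("coagulation removes the large, oxygen-rich, unsaturated end preferentially", {
  for (s in 1:3) {
    cfg <- synthetic_config(seed = s, n_formulas = 600, n_noise_peaks = 20)
    lib <- build_library(cfg)
    set.seed(100 + s)
    lo <- simulate_sample(lib, 0, cfg, "a")$truth$formula
    hi <- simulate_sample(lib, 10000, cfg, "b")$truth$formula
    a_lo <- annotate_formulas(lo); a_hi <- annotate_formulas(hi)
    expect_lt(mean(a_hi$neutral_mass), mean(a_lo$neutral_mass))
    expect_lt(mean(a_hi$o_c), mean(a_lo$o_c))
  }
})

test_that("iron-bearing formulas disappear along the iron gradient", {
  for (s in 1:3) {
    sim <- simulate_experiment(synthetic_config(seed = s, n_formulas = 600,
                                                n_noise_peaks = 20))
    counts <- sapply(seq_along(sim$config$fe_levels), function(i) {
      ids <- sprintf("inc_l%d_r%d", i, 1:3)
      length(unique(unlist(lapply(sim$truth$samples[ids], function(t) {
        f <- t$formula
        f[parse_formula(f)$Fe > 0]
      }))))
    })
    expect_lt(counts[length(counts)], counts[1])
    expect_true(all(diff(counts) <= 1))  # essentially monotone decline
  }
})

test_that("exact spectra are fully recovered in the no-noise limit", {
  cfg <- synthetic_config(seed = 23, n_formulas = 300, n_noise_peaks = 0,
                          ppm_noise_sd = 0, drift_amplitude = 0)
  lib <- build_library(cfg)
  set.seed(23)
  sim <- simulate_sample(lib, 0, cfg, "s")
  pl <- sim$replicates[[1]]
  a <- assign_peaklist(pl, reference = lib$formula[lib$is_calibrant])
  # every retained formula whose peak clears the detection limit is assigned
  mdl <- estimate_mdl(pl)
  tm <- mz_deprotonated(sim$truth$formula)
  near <- findInterval(tm, pl$mz + 1e-9) + 1L
  detectable <- near <= nrow(pl) & abs(pl$mz[pmin(near, nrow(pl))] - tm) < 1e-6 &
    pl$intensity[pmin(near, nrow(pl))] >= mdl
  expect_gt(mean(detectable), 0.9)
  # iron chelates can collide with series extensions of abundant CHO
  # families within sub-ppm windows even at perfect mass accuracy; every
  # other composition class must be recovered completely
  is_fe <- parse_formula(sim$truth$formula)$Fe > 0
  expect_equal(mean(sim$truth$formula[detectable & !is_fe] %in% a$formula), 1)
  expect_gte(mean(sim$truth$formula[detectable] %in% a$formula), 0.95)
})

test_that("chemistry scales as designed: ligand excess grows, SUP05 takes over", {
  sim <- small_sim()
  chem <- sim$chemistry[sim$chemistry$role == "incubation", ]
  lp <- tapply(chem$ligand_excess, chem$fe_nominal, mean)
  lp <- lp[order(as.numeric(names(lp)))]
  expect_true(all(diff(lp) >= 0))
  cov <- sim$covariates
  top <- cov[cov$fe == max(cov$fe), "SUP05"]
  expect_true(all(top >= 0.89))
  # one planted contaminated extract
  expect_identical(sum(sim$chemistry$spe_tdn > sim$chemistry$tdn,
                       na.rm = TRUE), 1L)
})

test_that("dataset round-trips through the directory format", {
  sim <- simulate_experiment(synthetic_config(seed = 24, n_formulas = 150,
                                              n_noise_peaks = 10))
  dir <- file.path(tempdir(), "ferrodom-sim")
  unlink(dir, recursive = TRUE)
  write_synthetic_dataset(sim, dir)
  back <- ferrodom:::load_synthetic_dataset(dir)
  id <- names(sim$peaklists)[[3]]
  expect_equal(back$peaklists[[id]][[1]]$mz, sim$peaklists[[id]][[1]]$mz)
  expect_equal(back$chemistry$dfe, sim$chemistry$dfe)
  expect_identical(back$calibrants, sim$calibrants)
})
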