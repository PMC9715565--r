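# Ground-truth synthetic data generator.
#
# Emulates the full experimental design the pipeline consumes: a DOM-like
# formula library, duplicate FT-ICR-MS measurements with calibration drift,
# ppm noise, 13C satellites and noise peaks, an Fe gradient with selective
# coagulation removal, a degradation-index gradient, endmember (plume /
# control) samples, scalar chemistry, and a microbial covariate table with
# planted formula-group links. Everything is deterministic given the seed.

#' Synthetic experiment configuration
#'
#' Defaults describe a 7-level Fe-gradient incubation in triplicate with
#' duplicate measurements, a 2000-formula DOM library over m/z 50-1000,
#' 0.1 ppm mass noise under a 0.3 ppm smooth calibration drift, and a
#' logistic Fe-coagulation removal model acting on standardised m/z, O/C,
#' 1/(H/C) and NOSC.
#'
#' @param seed Integer seed; fixed seed implies byte-identical outputs.
#' @param n_formulas Library size (default 2000).
#' @param mz_range Acquisition window in Da.
#' @param ppm_noise_sd Per-peak mass noise (ppm).
#' @param drift_amplitude Amplitude of the smooth per-measurement
#'   calibration drift (ppm).
#' @param n_noise_peaks Noise peaks per measurement, placed at least 1 ppm
#'   away from any library ion or satellite.
#' @param fe_levels Spiked Fe concentrations (umol/L).
#' @param n_replicates Incubation replicates per level.
#' @param n_measurements Measurement replicates per sample.
#' @param coagulation_strength Per-unit-log10(Fe+1) removal coefficients on
#'   standardised (m/z, O/C, 1/(H/C), NOSC).
#' @param baseline_logit Retention logit at zero Fe.
#' @param global_removal Composition-independent removal per log10(Fe+1).
#' @param fe_formula_removal Additional removal per log10(Fe+1) for
#'   iron-bearing formulas (co-precipitation of DOM-iron chelates).
#' @param degradation_gradient Target degradation index per Fe level.
#' @param endmember_ideg Target degradation index of the plume and control
#'   endmembers.
#' @param intensity_meanlog,intensity_sdlog Lognormal base intensities.
#' @param jitter_cv Relative intensity scatter between measurements.
#' @param noise_meanlog,noise_sdlog Lognormal noise-peak intensities.
#' @param abundance_profile 7 x 5 matrix of mean microbial group fractions
#'   per Fe level (columns Sulfurimonas, SUP05, Arcobacteraceae, Oleispira,
#'   Massilia); the default shifts from Sulfurimonas dominance to >= 0.89
#'   SUP05 at the highest level.
#' @param n_linked Planted group-linked formulas per linked group.
#' @return Object of class `synthetic_config`.
#' @export
synthetic_config <- function(seed = 1L,
                             n_formulas = 2000L,
                             mz_range = c(50, 1000),
                             ppm_noise_sd = 0.1,
                             drift_amplitude = 0.3,
                             n_noise_peaks = 300L,
                             fe_levels = c(0, 0.1, 1, 10, 100, 1000, 10000),
                             n_replicates = 3L,
                             n_measurements = 2L,
                             coagulation_strength = c(mz = 0.30, o_c = 0.25,
                                                      inv_hc = 0.15,
                                                      nosc = 0.10),
                             baseline_logit = 3,
                             global_removal = 0.6,
                             fe_formula_removal = 0.5,
                             degradation_gradient = c(0.80, 0.79, 0.74, 0.67,
                                                      0.69, 0.65, 0.61),
                             endmember_ideg = c(plume = 0.8, control = 0.3),
                             intensity_meanlog = log(5e6),
                             intensity_sdlog = 0.7,
                             jitter_cv = 0.08,
                             noise_meanlog = log(1e5),
                             noise_sdlog = 0.3,
                             abundance_profile = NULL,
                             n_linked = 3L) {
  if (is.null(abundance_profile)) {
    abundance_profile <- cbind(
      Sulfurimonas    = c(0.69, 0.80, 0.72, 0.59, 0.65, 0.30, 0.005),
      SUP05           = c(0.26, 0.15, 0.21, 0.35, 0.31, 0.62, 0.93),
      Arcobacteraceae = c(0.017, 0.004, 0.021, 0.017, 0.028, 0.030, 0.001),
      Oleispira       = c(0.012, 0.032, 0.047, 0.029, 0.009, 0.020, 0.001),
      Massilia        = c(0.001, 0.001, 0.001, 0.004, 0.001, 0.010, 0.030)
    )
  }
  cfg <- list(seed = as.integer(seed), n_formulas = as.integer(n_formulas),
              mz_range = mz_range, ppm_noise_sd = ppm_noise_sd,
              drift_amplitude = drift_amplitude,
              n_noise_peaks = as.integer(n_noise_peaks),
              fe_levels = fe_levels, n_replicates = as.integer(n_replicates),
              n_measurements = as.integer(n_measurements),
              coagulation_strength = coagulation_strength,
              baseline_logit = baseline_logit, global_removal = global_removal,
              fe_formula_removal = fe_formula_removal,
              degradation_gradient = degradation_gradient,
              endmember_ideg = endmember_ideg,
              intensity_meanlog = intensity_meanlog,
              intensity_sdlog = intensity_sdlog, jitter_cv = jitter_cv,
              noise_meanlog = noise_meanlog, noise_sdlog = noise_sdlog,
              abundance_profile = abundance_profile,
              n_linked = as.integer(n_linked))
  if (length(cfg$degradation_gradient) != length(cfg$fe_levels))
    stop("degradation_gradient must have one entry per Fe level")
  if (nrow(cfg$abundance_profile) != length(cfg$fe_levels))
    stop("abundance_profile must have one row per Fe level")
  class(cfg) <- "synthetic_config"
  cfg
}

# the four Fe-chelate compositions planted in every library
FE_PLANT <- c("C20H23FeN3O2", "C24H33FeN3O4", "C22H38FeO7S", "C17H30FeN6O8")

#' Build a synthetic DOM formula library
#'
#' Samples `n_formulas` unique compositions inside the assignment grid with
#' H/C in \[0.3, 2.2\] and O/C in (0, 1\], all passing the heteroatom
#' prohibition and elemental reduction rules. The library always contains
#' the ten degradation-index formulas, four Fe-chelate compositions,
#' planted CH2 and CO2 homologous series, a calibrant subset, a
#' blank-contaminant subset (including two formulas from the shipped
#' known-contaminant list) and group-linked formulas; lognormal base
#' intensities.
#'
#' @param cfg A [synthetic_config()].
#' @return data.frame: count columns, `formula`, `neutral_mass`, `mz`
#'   (\[M-H\]-), `base_intensity`, roles (`is_ideg_neg`, `is_ideg_pos`,
#'   `is_calibrant`, `is_blank_contaminant`, `linked_group`), and the
#'   standardised coagulation features `z_mz`, `z_oc`, `z_invhc`, `z_nosc`.
#' @export
build_library <- function(cfg = synthetic_config()) {
  set.seed(cfg$seed)
  em <- element_masses()
  # Marine DOM is organised in homologous series: the library is sampled as
  # CH2 ladders (with occasional CO2-linked branches) grown from base
  # compositions, which reproduces the dense series networks real spectra
  # show and which the series-resolution step of the assignment relies on.
  n_series <- ceiling(cfg$n_formulas / 6L)
  mass_t <- pmin(pmax(rnorm(n_series, 320, 110), 100), 650)
  hc <- pmin(pmax(rnorm(n_series, 1.25, 0.32), 0.35), 2.1)
  oc <- pmin(pmax(rnorm(n_series, 0.45, 0.16), 0.08), 0.9)
  C <- pmin(pmax(round(mass_t / (em[["C"]] + hc * em[["H"]] + oc * em[["O"]])), 5L), 45L)
  H <- pmin(pmax(round(hc * C), 1L), 2L * C + 2L)
  O <- pmin(pmax(round(oc * C), 1L), C)
  N <- ifelse(runif(n_series) < 0.22, sample(1:3, n_series, replace = TRUE), 0L)
  S <- ifelse(runif(n_series) < 0.06, 1L, 0L)
  P <- ifelse(runif(n_series) < 0.03, 1L, 0L)
  # respect O > 2P + S and the heteroatom prohibition rules
  S[O <= 2 * P + S] <- 0L
  P[O <= 2 * P + S] <- 0L
  drop_sp <- (N + S + P > 2L) & !(S == 0L & P == 0L)
  S[drop_sp] <- 0L; P[drop_sp] <- 0L
  # even-electron neutral molecules: H + N + P must be even (nitrogen rule)
  odd <- (H + N + P) %% 2L == 1L
  H[odd] <- ifelse(H[odd] + 1L <= 2L * C[odd] + 2L, H[odd] + 1L, H[odd] - 1L)

  # a subset of families carries one iron atom (DOM-iron chelates)
  Fe <- ifelse(runif(n_series) < 0.05, 1L, 0L)
  rows <- vector("list", n_series)
  len <- sample(4:10, n_series, replace = TRUE)
  branch <- runif(n_series) < 0.4
  for (i in seq_len(n_series)) {
    k <- 0:(len[i] - 1L)
    fam <- data.frame(C = C[i] + k, H = H[i] + 2L * k, N = N[i], O = O[i],
                      S = S[i], P = P[i], Cl = 0L, Fe = Fe[i])
    if (branch[i]) {
      j <- seq_len(sample(2:4, 1L))
      fam <- rbind(fam,
                   data.frame(C = C[i] + j, H = H[i], N = N[i],
                              O = O[i] + 2L * j, S = S[i], P = P[i],
                              Cl = 0L, Fe = Fe[i]))
    }
    rows[[i]] <- fam
  }
  ft <- do.call(rbind, rows)
  ok <- ft$C >= ft$O & ft$H <= 2 * ft$C + 2 & ft$H >= 1 & ft$C <= 100
  ft <- ft[ok, , drop = FALSE]
  ft$formula <- format_formula(ft)
  ft <- ft[!duplicated(ft$formula), , drop = FALSE]
  keep_mass <- monoisotopic_mass(ft[, ELEMENTS]) - PROTON_MASS
  ft <- ft[keep_mass >= cfg$mz_range[1] & keep_mass <= cfg$mz_range[2], ,
           drop = FALSE]

  plant <- parse_formula(c(IDEG_NEG, IDEG_POS, FE_PLANT,
                           "C18H34O2", "C16H32O2"))
  plant$formula <- format_formula(plant)

  lib <- rbind(plant, ft[!ft$formula %in% plant$formula,
                         c(ELEMENTS, "formula")])
  lib <- lib[seq_len(min(cfg$n_formulas, nrow(lib))), , drop = FALSE]
  rownames(lib) <- NULL

  lib$neutral_mass <- monoisotopic_mass(lib[, ELEMENTS])
  lib$mz <- lib$neutral_mass - PROTON_MASS
  lib$base_intensity <- rlnorm(nrow(lib), cfg$intensity_meanlog,
                               cfg$intensity_sdlog)
  lib$is_ideg_neg <- lib$formula %in% IDEG_NEG
  lib$is_ideg_pos <- lib$formula %in% IDEG_POS
  lib$is_fe <- lib$Fe > 0L

  # blank-contaminant subset: two known contaminants plus random members
  lib$is_blank_contaminant <- lib$formula %in% c("C18H34O2", "C16H32O2")
  free <- which(!lib$is_blank_contaminant & !lib$is_ideg_neg &
                  !lib$is_ideg_pos & !lib$is_fe)
  lib$is_blank_contaminant[sample(free, 10L)] <- TRUE

  # calibrants: ubiquitous formulas spread across the mass axis, emulating
  # the internal calibration list of an in-house DOM reference standard;
  # the ten degradation-index masses are classic abundant DOM peaks and
  # always belong to such lists
  free <- which(!lib$is_blank_contaminant & !lib$is_fe)
  ord <- free[order(lib$mz[free])]
  n_cal <- max(60L, round(0.08 * nrow(lib)))
  lib$is_calibrant <- FALSE
  lib$is_calibrant[ord[round(seq(1, length(ord), length.out = n_cal))]] <- TRUE
  lib$is_calibrant[lib$is_ideg_neg | lib$is_ideg_pos] <- TRUE

  # group-linked formulas (CHO, unflagged)
  lib$linked_group <- NA_character_
  free <- which(lib$N == 0L & lib$S == 0L & lib$P == 0L & lib$Fe == 0L &
                  !lib$is_blank_contaminant & !lib$is_calibrant &
                  !lib$is_ideg_neg & !lib$is_ideg_pos)
  linked <- sample(free, 2L * cfg$n_linked)
  lib$linked_group[linked[seq_len(cfg$n_linked)]] <- "SUP05"
  lib$linked_group[linked[cfg$n_linked + seq_len(cfg$n_linked)]] <- "Sulfurimonas"

  # standardised coagulation features
  invhc <- lib$C / lib$H
  feats <- cbind(mz = lib$mz, o_c = lib$O / lib$C, inv_hc = invhc,
                 nosc = nosc(lib[, ELEMENTS]))
  z <- scale(feats)
  lib$z_mz <- z[, "mz"]; lib$z_oc <- z[, "o_c"]
  lib$z_invhc <- z[, "inv_hc"]; lib$z_nosc <- z[, "nosc"]
  attr(lib, "feature_center") <- attr(z, "scaled:center")
  attr(lib, "feature_scale") <- attr(z, "scaled:scale")
  lib
}

# expected sample-level intensity of every library formula, with the
# degradation-index formulas pinned so that their raw-intensity ratio equals
# the target I_DEG
sample_intensities <- function(lib, cfg, ideg_target, abundances = NULL) {
  int <- lib$base_intensity
  A <- 2 * exp(cfg$intensity_meanlog)
  int[lib$is_ideg_neg] <- A * ideg_target
  int[lib$is_ideg_pos] <- A * (1 - ideg_target)
  if (!is.null(abundances)) {
    for (g in names(abundances)) {
      sel <- which(!is.na(lib$linked_group) & lib$linked_group == g)
      int[sel] <- lib$base_intensity[sel] * (0.3 + 2.5 * abundances[[g]])
    }
  }
  int
}

# survival probability of every formula at one Fe level
survival_prob <- function(lib, fe, cfg) {
  lf <- log10(fe + 1)
  cs <- cfg$coagulation_strength
  eta <- cfg$baseline_logit - lf *
    (cfg$global_removal + cs[["mz"]] * lib$z_mz + cs[["o_c"]] * lib$z_oc +
       cs[["inv_hc"]] * lib$z_invhc + cs[["nosc"]] * lib$z_nosc +
       cfg$fe_formula_removal * (lib$Fe > 0L))
  p <- plogis(eta)
  # index, calibrant and group-linked formulas are ubiquitous by design so
  # the degradation gradient, recalibration and group links stay observable
  p[lib$is_ideg_neg | lib$is_ideg_pos | lib$is_calibrant |
      !is.na(lib$linked_group)] <- 1
  p
}

# turn expected intensities of retained formulas into measurement replicate
# peak lists: intensity jitter, smooth drift + ppm noise on the mass axis,
# 13C satellites, noise peaks
measure_replicates <- function(lib, retained, exp_int, cfg, sample_id,
                               is_blank = FALSE) {
  out <- vector("list", cfg$n_measurements)
  ion_mz <- lib$mz
  for (r in seq_len(cfg$n_measurements)) {
    phase <- runif(1, 0, 2 * pi)
    amp <- cfg$drift_amplitude * runif(1, 0.5, 1)
    mz0 <- ion_mz[retained]
    drift <- amp * sin(2 * pi * (mz0 - cfg$mz_range[1]) /
                         diff(cfg$mz_range) + phase)
    ppm_err <- drift + rnorm(length(mz0), 0, cfg$ppm_noise_sd)
    mz_obs <- mz0 * (1 + ppm_err * 1e-6)
    int_obs <- exp_int[retained] *
      rlnorm(length(mz0), -cfg$jitter_cv^2 / 2, cfg$jitter_cv)
    # 13C satellites at +1.0033548 with the expected per-carbon abundance
    sat_mz <- mz_obs + C13_DELTA
    sat_int <- C13_ABUNDANCE * lib$C[retained] * int_obs *
      rlnorm(length(mz0), 0, 0.15)
    # noise peaks >= 1 ppm away from any library ion or satellite
    protected <- sort(c(ion_mz, ion_mz + C13_DELTA))
    noise_mz <- numeric(0)
    while (length(noise_mz) < cfg$n_noise_peaks) {
      prop <- runif(2L * cfg$n_noise_peaks, cfg$mz_range[1], cfg$mz_range[2])
      i <- findInterval(prop, protected)
      d_lo <- ifelse(i >= 1, prop - protected[pmax(i, 1)], Inf)
      d_hi <- ifelse(i < length(protected),
                     protected[pmin(i + 1, length(protected))] - prop, Inf)
      okp <- pmin(d_lo, d_hi) > prop * 1e-6
      noise_mz <- c(noise_mz, prop[okp])
    }
    noise_mz <- noise_mz[seq_len(cfg$n_noise_peaks)]
    noise_int <- rlnorm(cfg$n_noise_peaks, cfg$noise_meanlog, cfg$noise_sdlog)

    mz_all <- c(mz_obs, sat_mz, noise_mz)
    int_all <- c(int_obs, sat_int, noise_int)
    ord <- order(mz_all)
    mz_all <- mz_all[ord]; int_all <- int_all[ord]
    # merge coincident centroids (within instrument resolution)
    grpid <- cumsum(c(TRUE, diff(mz_all) >= 1e-6))
    mz_all <- tapply(mz_all, grpid, `[`, 1L)
    int_all <- tapply(int_all, grpid, sum)
    out[[r]] <- peaklist(as.numeric(mz_all), as.numeric(int_all),
                         sample_id = sample_id, replicate_id = r,
                         is_blank = is_blank)
  }
  out
}

#' Simulate one incubation sample
#'
#' Applies the logistic Fe-coagulation survival model to the library,
#' draws the retained formula set, and produces the measurement replicate
#' peak lists together with the ground-truth table. Uses the current RNG
#' state ([simulate_experiment()] seeds the stream once).
#'
#' @param lib Library from [build_library()].
#' @param fe_level Spiked Fe (umol/L).
#' @param cfg A [synthetic_config()].
#' @param sample_id Sample identifier.
#' @param ideg_target Degradation-index target (default from the gradient
#'   entry matching `fe_level`).
#' @param abundances Optional named microbial group abundances used for the
#'   planted group-linked formulas.
#' @return List: `truth` (retained formulas with expected intensities and
#'   survival probabilities), `replicates` (list of [peaklist()]s).
#' @export
simulate_sample <- function(lib, fe_level, cfg = synthetic_config(),
                            sample_id = "sample", ideg_target = NULL,
                            abundances = NULL) {
  if (is.null(ideg_target)) {
    i <- match(fe_level, cfg$fe_levels)
    ideg_target <- if (!is.na(i)) cfg$degradation_gradient[i] else 0.7
  }
  p <- survival_prob(lib, fe_level, cfg)
  retained <- which(rbinom(nrow(lib), 1L, p) == 1L)
  exp_int <- sample_intensities(lib, cfg, ideg_target, abundances)
  reps <- measure_replicates(lib, retained, exp_int, cfg, sample_id)
  truth <- data.frame(formula = lib$formula[retained],
                      expected_intensity = exp_int[retained],
                      survival_prob = p[retained],
                      stringsAsFactors = FALSE)
  list(truth = truth, replicates = reps)
}

#' Simulate a complete Fe-gradient incubation experiment
#'
#' Generates everything the pipeline consumes with known ground truth:
#' peak lists for every Fe level x incubation replicate (duplicate
#' measurements each), plume and control endmember samples with distinct
#' composition and degradation state, solvent blank measurements carrying
#' the blank-contaminant subset, scalar chemistry (dFe with a contaminated
#' control blank, increasing ligand excess, DOC/TDN/SPE quantities, one
#' planted SPE-TDN contamination), and per-replicate microbial covariates
#' with the SUP05 takeover at the highest Fe level.
#'
#' @param cfg A [synthetic_config()].
#' @return Object of class `dom_simulation`: list with `config`, `library`,
#'   `peaklists` (named list), `blanks`, `chemistry`, `covariates`,
#'   `calibrants`, `truth` (per-sample tables plus the coagulation model).
#' @export
simulate_experiment <- function(cfg = synthetic_config()) {
  lib <- build_library(cfg)   # seeds the RNG stream
  peaklists <- list()
  truth <- list()
  chem <- list()
  cov <- list()

  # --- endmembers -----------------------------------------------------
  # plume: near-complete library, degraded signature
  p_keep <- plogis(2.5 + 0 * lib$z_mz)
  p_keep[lib$is_ideg_neg | lib$is_ideg_pos | lib$is_calibrant |
           !is.na(lib$linked_group)] <- 1
  retained <- which(rbinom(nrow(lib), 1L, p_keep) == 1L)
  exp_int <- sample_intensities(lib, cfg, cfg$endmember_ideg[["plume"]])
  peaklists[["plume"]] <- measure_replicates(lib, retained, exp_int, cfg, "plume")
  truth[["plume"]] <- data.frame(formula = lib$formula[retained],
                                 expected_intensity = exp_int[retained])
  chem[["plume"]] <- data.frame(sample = "plume", role = "plume",
                                fe_nominal = NA, replicate = 1,
                                dfe = 0.071, ligand_excess = 0.143, doc = 75,
                                spe_doc = 20, tdn = 35.2, spe_tdn = 0.9,
                                flag = "", stringsAsFactors = FALSE)

  # controls: fresh, low-mass-biased composition, small richness
  for (k in 1:3) {
    id <- paste0("control_", k)
    p_keep <- plogis(-0.5 - 1.2 * lib$z_mz)
    p_keep[lib$is_ideg_neg | lib$is_ideg_pos | lib$is_calibrant] <- 1
    retained <- which(rbinom(nrow(lib), 1L, p_keep) == 1L)
    exp_int <- sample_intensities(lib, cfg, cfg$endmember_ideg[["control"]])
    peaklists[[id]] <- measure_replicates(lib, retained, exp_int, cfg, id)
    truth[[id]] <- data.frame(formula = lib$formula[retained],
                              expected_intensity = exp_int[retained])
    # replicate 1 carries a handling-contamination dFe outlier
    dfe <- if (k == 1L) 0.69 else 0.30 * (1 + rnorm(1, 0, 0.02))
    chem[[id]] <- data.frame(sample = id, role = "control", fe_nominal = 0,
                             replicate = k, dfe = dfe,
                             ligand_excess = if (k == 2L) 0.03 else NA,
                             doc = 850 * (1 + rnorm(1, 0, 0.1)),
                             spe_doc = 8 * (1 + rnorm(1, 0, 0.15)),
                             tdn = 495 * (1 + rnorm(1, 0, 0.02)),
                             spe_tdn = 0.5 * (1 + rnorm(1, 0, 0.2)),
                             flag = if (k == 1L) "star" else "",
                             stringsAsFactors = FALSE)
  }

  # --- incubations ----------------------------------------------------
  groups <- character(0)
  for (i in seq_along(cfg$fe_levels)) {
    fe <- cfg$fe_levels[i]
    for (r in seq_len(cfg$n_replicates)) {
      id <- sprintf("inc_l%d_r%d", i, r)
      ab <- cfg$abundance_profile[i, ]
      ab <- plogis(qlogis(pmin(pmax(ab, 1e-4), 1 - 1e-4)) + rnorm(length(ab), 0, 0.15))
      if (i == length(cfg$fe_levels))  # SUP05 takeover is a hard target
        ab[["SUP05"]] <- min(max(ab[["SUP05"]], 0.89), 0.975)
      sim <- simulate_sample(lib, fe, cfg, sample_id = id,
                             ideg_target = cfg$degradation_gradient[i],
                             abundances = as.list(ab))
      peaklists[[id]] <- sim$replicates
      truth[[id]] <- sim$truth
      contaminated <- (i == 2L && r == 3L)  # planted SPE-TDN contamination
      tdn <- 4 * (1 + rnorm(1, 0, 0.2))
      chem[[id]] <- data.frame(sample = id, role = "incubation",
                               fe_nominal = fe, replicate = r,
                               dfe = (fe + 0.3) * (1 + rnorm(1, 0, 0.03)),
                               ligand_excess = 0.03 * (1 + 1.5 * log10(fe + 1)) *
                                 (1 + rnorm(1, 0, 0.02)),
                               doc = 500 * (1 + rnorm(1, 0, 0.2)),
                               spe_doc = 25 * (1 + rnorm(1, 0, 0.15)),
                               tdn = tdn,
                               spe_tdn = if (contaminated) 2 * tdn
                                         else 1.2 * (1 + rnorm(1, 0, 0.2)),
                               flag = if (contaminated) "dagger" else "",
                               stringsAsFactors = FALSE)
      cov[[id]] <- data.frame(sample = id, fe = fe, t(ab),
                              stringsAsFactors = FALSE)
      groups <- c(groups, sprintf("fe_%g", fe))
    }
  }

  # --- blanks ---------------------------------------------------------
  blanks <- list()
  for (b in c("blank_methanol", "blank_water")) {
    sel <- which(lib$is_blank_contaminant)
    exp_int <- 2 * lib$base_intensity
    blanks[[b]] <- measure_replicates(lib, sel, exp_int, cfg, b,
                                      is_blank = TRUE)[[1L]]
  }

  structure(list(
    config = cfg,
    library = lib,
    peaklists = peaklists,
    blanks = blanks,
    chemistry = do.call(rbind, c(chem, make.row.names = FALSE)),
    covariates = do.call(rbind, c(cov, make.row.names = FALSE)),
    calibrants = lib$formula[lib$is_calibrant],
    truth = list(samples = truth,
                 coagulation = cfg$coagulation_strength,
                 global_removal = cfg$global_removal,
                 baseline_logit = cfg$baseline_logit),
    groups = groups
  ), class = "dom_simulation")
}

#' Recover the coagulation coefficients from a simulation
#'
#' Fits the generating logistic survival model to the per-sample retention
#' ground truth: retention ~ log10(Fe+1) and its interactions with the
#' standardised composition features (m/z, O/C, 1/(H/C), NOSC) and the
#' iron-formula indicator. Formulas pinned to full retention (calibrants,
#' index and group-linked formulas) are excluded. The negated interaction
#' coefficients estimate `coagulation_strength`.
#'
#' @param sim A `dom_simulation`.
#' @return data.frame with `term`, `true`, `estimated`, `relative_bias`.
#' @export
recover_coagulation <- function(sim) {
  lib <- sim$library
  exempt <- lib$is_calibrant | lib$is_ideg_neg | lib$is_ideg_pos |
    !is.na(lib$linked_group)
  ids <- grep("^inc_", names(sim$truth$samples), value = TRUE)
  fe <- setNames(sim$chemistry$fe_nominal, sim$chemistry$sample)
  dat <- do.call(rbind, lapply(ids, function(id) {
    data.frame(y = as.integer(lib$formula %in% sim$truth$samples[[id]]$formula),
               lf = log10(fe[[id]] + 1), z_mz = lib$z_mz, z_oc = lib$z_oc,
               z_invhc = lib$z_invhc, z_nosc = lib$z_nosc,
               is_fe = as.numeric(lib$Fe > 0))[!exempt, ]
  }))
  fit <- glm(y ~ lf + lf:z_mz + lf:z_oc + lf:z_invhc + lf:z_nosc + lf:is_fe,
             family = binomial(), data = dat)
  est <- -coef(fit)[c("lf:z_mz", "lf:z_oc", "lf:z_invhc", "lf:z_nosc",
                      "lf:is_fe")]
  true <- c(sim$config$coagulation_strength[c("mz", "o_c", "inv_hc", "nosc")],
            sim$config$fe_formula_removal)
  data.frame(term = c("mz", "o_c", "inv_hc", "nosc", "fe_formula"),
             true = unname(true), estimated = unname(est),
             relative_bias = unname((est - true) / true))
}

#' @export
print.dom_simulation <- function(x, ...) {
  cat(sprintf(paste0("<dom_simulation> %d library formulas; %d samples x %d ",
                     "measurements; %d blanks; seed %d\n"),
              nrow(x$library), length(x$peaklists),
              x$config$n_measurements, length(x$blanks), x$config$seed))
  invisible(x)
}

#' Write a simulated dataset as a directory of delimited text files
#'
#' Emits `peaklists/*.csv`, `blanks/*.csv`, `chemistry.csv`,
#' `covariates.csv`, `calibrants.txt`, `truth/*.csv` and a YAML config
#' snapshot.
#'
#' @param sim A `dom_simulation`.
#' @param dir Output directory (created).
#' @return `dir`, invisibly.
#' @export
write_synthetic_dataset <- function(sim, dir) {
  dir.create(file.path(dir, "peaklists"), recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(dir, "blanks"), showWarnings = FALSE)
  dir.create(file.path(dir, "truth"), showWarnings = FALSE)
  for (id in names(sim$peaklists)) {
    for (r in seq_along(sim$peaklists[[id]])) {
      write_peaklist(sim$peaklists[[id]][[r]],
                     file.path(dir, "peaklists", sprintf("%s_m%d.csv", id, r)))
    }
  }
  for (b in names(sim$blanks))
    write_peaklist(sim$blanks[[b]], file.path(dir, "blanks", paste0(b, ".csv")))
  write.csv(sim$chemistry, file.path(dir, "chemistry.csv"), row.names = FALSE)
  write.csv(sim$covariates, file.path(dir, "covariates.csv"), row.names = FALSE)
  writeLines(sim$calibrants, file.path(dir, "calibrants.txt"))
  for (id in names(sim$truth$samples))
    write.csv(sim$truth$samples[[id]],
              file.path(dir, "truth", paste0(id, ".csv")), row.names = FALSE)
  cfg <- sim$config
  cfg$abundance_profile <- apply(cfg$abundance_profile, 1L, as.list)
  yaml::write_yaml(unclass(cfg), file.path(dir, "config.yaml"))
  invisible(dir)
}
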