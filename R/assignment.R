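# Molecular formula assignment for negative-ESI FT-ICR-MS peak lists.
#
# Stage order inside assign_peaklist(): m/z range filter -> method detection
# limit -> recalibration against reference formulas -> candidate enumeration
# on the composition grid (< 0.5 ppm) -> homologous-series resolution of
# multiple candidates -> 13C isotopologue verification.

#' Heteroatom prohibition rules
#'
#' Combinations mixing N, S and P are chemically implausible in marine DOM
#' spectra and are excluded from the candidate grid: any composition with
#' three or more N+S+P heteroatoms is rejected unless it is a pure nitrogen
#' composition with 3-6 N (this single rule subsumes the banned NSP, N2-4S,
#' N2-4P, NS2, N2-4S2 and S2P blocks). Cl and Fe never disqualify.
#'
#' @param ft Formula count table or character vector.
#' @return Logical vector, TRUE where the composition is admissible.
#' @export
#' @examples
#' allowed_heteroatoms(formula_table(C = 10, H = 14, N = 1, O = 4, S = 1, P = 1))
allowed_heteroatoms <- function(ft) {
  ft <- as_formula_table(ft)
  het <- ft$N + ft$S + ft$P
  het <= 2L | (ft$S == 0L & ft$P == 0L & ft$N >= 3L & ft$N <= 6L)
}

# admissible (N, S, P, Cl, Fe) blocks of the grid with their partial masses
heteroatom_blocks <- function(grid = formula_grid()) {
  blocks <- expand.grid(N = grid$N[1]:grid$N[2], S = grid$S[1]:grid$S[2],
                        P = grid$P[1]:grid$P[2], Cl = grid$Cl[1]:grid$Cl[2],
                        Fe = grid$Fe[1]:grid$Fe[2])
  ok <- allowed_heteroatoms(formula_table(C = 1L, H = 1L, N = blocks$N,
                                          O = 1L, S = blocks$S, P = blocks$P,
                                          Cl = blocks$Cl, Fe = blocks$Fe))
  blocks <- blocks[ok, , drop = FALSE]
  em <- element_masses()
  mass <- blocks$N * em[["N"]] + blocks$S * em[["S"]] + blocks$P * em[["P"]] +
    blocks$Cl * em[["Cl"]] + blocks$Fe * em[["Fe"]]
  list(counts = as.matrix(blocks), mass = mass)
}

#' Enumerate candidate formulas for neutral masses
#'
#' Returns every grid composition whose monoisotopic mass lies within
#' `tol_ppm` of each target neutral mass and passes the heteroatom
#' prohibition rules. The search loops over heteroatom blocks and oxygen and
#' completes C/H in closed form; it is exactly equivalent to brute-force
#' enumeration of the grid (property-tested against an independent oracle).
#'
#' @param neutral_mass Numeric vector of neutral masses (Da).
#' @param tol_ppm Mass tolerance in ppm (default 0.5, strict `<`).
#' @param grid Composition bounds, see [formula_grid()].
#' @return data.frame with `peak` (index into `neutral_mass`), the count
#'   columns, `neutral_mass`, `error_ppm` and `formula`; within each peak
#'   ordered by ascending |error|, ties by formula string.
#' @export
#' @examples
#' enumerate_candidates(monoisotopic_mass("C15H14O6"))
enumerate_candidates <- function(neutral_mass, tol_ppm = 0.5,
                                 grid = formula_grid()) {
  stopifnot(tol_ppm > 0)
  hb <- heteroatom_blocks(grid)
  em <- element_masses()
  out <- enumerate_grid_cpp(as.numeric(neutral_mass), tol_ppm,
                            hb$counts, hb$mass,
                            grid$C[1], grid$C[2], grid$H[1], grid$H[2],
                            grid$O[1], grid$O[2],
                            em[["C"]], em[["H"]], em[["O"]])
  out <- as.data.frame(out)
  if (nrow(out)) {
    out$formula <- format_formula(out)
    out <- out[order(out$peak, abs(out$error_ppm), out$formula), , drop = FALSE]
    rownames(out) <- NULL
  } else {
    out$formula <- character(0)
  }
  out
}

#' Method detection limit
#'
#' Intensity threshold below which peaks are treated as noise:
#' mean + 2 SD of the noise-intensity population, estimated from the
#' lowest-intensity decile of the peak list (a deterministic, scale-free
#' noise proxy).
#'
#' @param pl A [peaklist()].
#' @param noise_quantile Fraction of lowest-intensity peaks regarded as the
#'   noise population (default 0.1).
#' @return Intensity threshold (0 with a warning when fewer than 20 peaks).
#' @export
estimate_mdl <- function(pl, noise_quantile = 0.1) {
  if (nrow(pl) == 0L) stop("empty peak list")
  if (nrow(pl) < 20L) {
    warning("fewer than 20 peaks; method detection limit set to 0")
    return(0)
  }
  cut <- quantile(pl$intensity, noise_quantile, names = FALSE)
  noise <- pl$intensity[pl$intensity <= cut]
  s <- if (length(noise) > 1L) sd(noise) else 0
  mean(noise) + 2 * s
}

#' Remove peaks below the method detection limit
#'
#' @param pl A [peaklist()].
#' @param mdl Threshold from [estimate_mdl()] (recomputed when missing).
#' @return Filtered peaklist with attribute `mdl`.
#' @export
apply_mdl <- function(pl, mdl = estimate_mdl(pl)) {
  keep <- pl$intensity >= mdl
  out <- peaklist_like(pl, pl$mz[keep], pl$intensity[keep])
  attr(out, "mdl") <- mdl
  out
}

#' Recalibrate a peak list against reference formulas
#'
#' Matches deprotonated reference masses to observed peaks inside a coarse
#' window, summarises the signed ppm errors with a running median over
#' overlapping mass windows (nonparametric smoothing), interpolates the
#' resulting correction curve across the whole m/z axis and removes it from
#' every peak. If the corrected reference errors are not at least as good as
#' before (by median |error|) the original list is returned, so
#' recalibration never degrades calibration.
#'
#' @param pl A [peaklist()].
#' @param reference Character vector (or count table) of calibration
#'   formulas whose \[M-H\]- ions are expected in the spectrum.
#' @param match_ppm Coarse matching window in ppm (default 2).
#' @param window_da Width of the running-median window in Da (default 50).
#' @return Recalibrated peaklist with attribute `recalibration`
#'   (data.frame of matches plus before/after median |error|).
#' @export
recalibrate <- function(pl, reference, match_ppm = 2, window_da = 50) {
  ref_mz <- sort(mz_deprotonated(as_formula_table(reference)))
  idx <- findInterval(ref_mz, pl$mz)
  near <- function(i, r) {
    cand <- c(i, i + 1L)
    cand <- cand[cand >= 1L & cand <= nrow(pl)]
    cand[which.min(abs(pl$mz[cand] - r))]
  }
  hit <- mapply(near, idx, ref_mz)
  err <- (pl$mz[hit] - ref_mz) / ref_mz * 1e6
  ok <- is.finite(err) & abs(err) <= match_ppm
  matches <- data.frame(ref_mz = ref_mz[ok], peak_mz = pl$mz[hit[ok]],
                        error_ppm = err[ok])
  if (nrow(matches) < 5L) {
    warning("fewer than 5 reference matches; returning peak list unchanged")
    attr(pl, "recalibration") <- list(matches = matches, applied = FALSE)
    return(pl)
  }
  matches <- matches[order(matches$peak_mz), , drop = FALSE]
  # running median in overlapping windows centred on each match
  half <- window_da / 2
  knot <- vapply(matches$peak_mz, function(m) {
    median(matches$error_ppm[abs(matches$peak_mz - m) <= half])
  }, numeric(1))
  # corrections below 0.01 ppm are physically meaningless; applying them
  # would only churn an already-calibrated axis
  if (max(abs(knot)) < 0.01) {
    attr(pl, "recalibration") <- list(matches = matches, applied = FALSE,
                                      median_abs_before = median(abs(matches$error_ppm)),
                                      median_abs_after = median(abs(matches$error_ppm)))
    return(pl)
  }
  corr <- approx(matches$peak_mz, knot, xout = pl$mz, rule = 2, ties = mean)$y
  mz_new <- pl$mz / (1 + corr * 1e-6)
  out <- peaklist_like(pl, mz_new, pl$intensity)
  err_after <- (mz_new[hit][ok] - ref_mz[ok]) / ref_mz[ok] * 1e6
  before <- median(abs(matches$error_ppm))
  after <- median(abs(err_after))
  if (after > before) {
    attr(pl, "recalibration") <- list(matches = matches, applied = FALSE,
                                      median_abs_before = before,
                                      median_abs_after = before)
    return(pl)
  }
  attr(out, "recalibration") <- list(matches = matches, applied = TRUE,
                                     median_abs_before = before,
                                     median_abs_after = after)
  out
}

# series keys: along a CH2 ladder all elements except C,H are shared and
# H - 2C is invariant; along a CO2 ladder all except C,O are shared and
# O - 2C is invariant
series_keys <- function(cand) {
  list(
    ch2 = paste(cand$N, cand$O, cand$S, cand$P, cand$Cl, cand$Fe,
                cand$H - 2L * cand$C),
    co2 = paste(cand$H, cand$N, cand$S, cand$P, cand$Cl, cand$Fe,
                cand$O - 2L * cand$C)
  )
}

#' Resolve multiple candidates through homologous-series networks
#'
#' Peaks with a single candidate seed the assigned set; for ambiguous peaks
#' each candidate is scored by how many already-assigned formulas it joins
#' along CH2 or CO2 homologous series (differing by integer multiples of one
#' unit). The highest score wins, ties broken by smaller |ppm error| then
#' lexicographic formula. Selection is repeated for a bounded number of
#' passes so newly chosen formulas can inform the remaining ambiguities.
#'
#' @param cand Candidate table from [enumerate_candidates()].
#' @param max_passes Maximum scoring passes (default 3).
#' @param prior Optional formulas known to be present (e.g. the internal
#'   calibration list) that seed the assigned set alongside the
#'   unique-candidate peaks.
#' @return data.frame with one row per peak that has at least one candidate:
#'   count columns, `neutral_mass`, `error_ppm`, `formula`, `series_score`.
#' @export
resolve_by_series <- function(cand, max_passes = 3L, prior = NULL) {
  if (nrow(cand) == 0L)
    return(cbind(cand, series_score = integer(0)))
  keys <- series_keys(cand)
  cand$.ch2 <- keys$ch2
  cand$.co2 <- keys$co2
  # count how many formulas of `set` each row of `rows` joins along a CH2 or
  # CO2 ladder; the row's own formula (sharing both keys) never counts
  score_rows <- function(rows, set) {
    uniq <- !duplicated(set$formula)
    ch2_tab <- table(set$.ch2[uniq])
    co2_tab <- table(set$.co2[uniq])
    in_set <- rows$formula %in% set$formula
    s_ch2 <- as.integer(ch2_tab[rows$.ch2]); s_ch2[is.na(s_ch2)] <- 0L
    s_co2 <- as.integer(co2_tab[rows$.co2]); s_co2[is.na(s_co2)] <- 0L
    s_ch2 + s_co2 - 2L * as.integer(in_set)
  }
  n_cand <- table(cand$peak)
  sel <- cand$peak %in% as.integer(names(n_cand)[n_cand == 1L])
  chosen <- cand[sel, , drop = FALSE]          # unique-candidate seeds
  if (!is.null(prior)) {
    pf <- as_formula_table(prior)
    pf <- data.frame(peak = NA_integer_, pf,
                     neutral_mass = monoisotopic_mass(pf),
                     error_ppm = 0, formula = format_formula(pf))
    pk <- series_keys(pf)
    pf$.ch2 <- pk$ch2; pf$.co2 <- pk$co2
    chosen <- rbind(chosen, pf[, names(chosen), drop = FALSE])
  }
  multi <- cand[!sel, , drop = FALSE]
  # grow the network conservatively: a pass only commits candidates with
  # positive series support, so unsupported near-ties cannot pollute the
  # assigned set; whatever remains unsupported after the final pass is
  # settled by the tie-break rule alone
  for (pass in seq_len(max_passes)) {
    if (nrow(multi) == 0L) break
    multi$series_score <- score_rows(multi, chosen)
    ord <- order(multi$peak, -multi$series_score, abs(multi$error_ppm),
                 multi$formula)
    m_ord <- multi[ord, , drop = FALSE]
    pick <- m_ord[!duplicated(m_ord$peak), , drop = FALSE]
    commit <- if (pass < max_passes) pick[pick$series_score > 0L, , drop = FALSE]
              else pick
    if (nrow(commit) == 0L && pass < max_passes) next
    chosen <- rbind(chosen, commit[, names(chosen), drop = FALSE])
    multi <- multi[!multi$peak %in% commit$peak, , drop = FALSE]
  }
  out <- chosen[!is.na(chosen$peak), , drop = FALSE]
  out <- out[order(out$peak), , drop = FALSE]
  out$series_score <- score_rows(out, out)
  out$.ch2 <- NULL; out$.co2 <- NULL
  rownames(out) <- NULL
  out
}

#' Flag 13C isotopologue peaks
#'
#' A peak is flagged as a 13C satellite when a peak one 13C-12C mass
#' difference below it exists whose intensity makes the pair plausible as
#' parent and isotopologue (satellite no stronger than `max_ratio` times
#' the parent). Satellite peaks are not monoisotopic ions and are excluded
#' from formula assignment; they remain in the peak list for verification.
#'
#' @param pl A [peaklist()].
#' @param tol_ppm Matching tolerance (default 1).
#' @param max_ratio Maximum satellite/parent intensity ratio (default 0.6,
#'   the expectation for ~50 carbon atoms).
#' @return Logical vector over peaks.
#' @export
flag_isotopologues <- function(pl, tol_ppm = 1, max_ratio = 0.6) {
  parent_mz <- pl$mz - C13_DELTA
  tol <- pl$mz * tol_ppm * 1e-6
  idx <- findInterval(parent_mz, pl$mz)
  flag <- logical(nrow(pl))
  for (j in seq_len(nrow(pl))) {
    cand <- c(idx[j], idx[j] + 1L)
    cand <- cand[cand >= 1L & cand <= nrow(pl)]
    cand <- cand[abs(pl$mz[cand] - parent_mz[j]) <= tol[j]]
    if (length(cand) && any(pl$intensity[j] <= max_ratio * pl$intensity[cand]))
      flag[j] <- TRUE
  }
  flag
}

#' Verify assignments through 13C isotopologues
#'
#' For assigned peaks above an intensity floor the 13C satellite is sought at
#' m/z + 1.0033548; its expected relative intensity is 0.011 per carbon atom.
#' Assignments whose satellite is absent or whose observed/expected ratio
#' falls outside `ratio_window` are flagged unverified and dropped from the
#' verified output. Peaks below the floor are retained untested
#' (`isotope_verified = NA`).
#'
#' @param assigned Assignment table (must carry `mz`, `intensity`, `C`).
#' @param pl The peak list the assignments came from.
#' @param mdl Method detection limit used for the floor.
#' @param floor_mult Intensity floor as a multiple of `mdl` (default 20).
#' @param ratio_window Acceptable observed/expected satellite intensity ratio
#'   (default c(0.2, 5); FT-ICR intensity ratios are noisy).
#' @param sat_tol_ppm Satellite matching tolerance in ppm (default 1).
#' @param drop_unverified Drop rows with `isotope_verified == FALSE`
#'   (default TRUE).
#' @return Assignment table with an `isotope_verified` column.
#' @export
verify_isotopes <- function(assigned, pl, mdl, floor_mult = 20,
                            ratio_window = c(0.2, 5), sat_tol_ppm = 1,
                            drop_unverified = TRUE) {
  if (nrow(assigned) == 0L) {
    assigned$isotope_verified <- logical(0)
    return(assigned)
  }
  floor <- floor_mult * mdl
  verified <- rep(NA, nrow(assigned))
  test <- which(assigned$intensity >= floor)
  if (length(test)) {
    sat_mz <- assigned$mz[test] + C13_DELTA
    tol <- sat_mz * sat_tol_ppm * 1e-6
    idx <- findInterval(sat_mz, pl$mz)
    for (j in seq_along(test)) {
      cand <- c(idx[j], idx[j] + 1L)
      cand <- cand[cand >= 1L & cand <= nrow(pl)]
      cand <- cand[abs(pl$mz[cand] - sat_mz[j]) <= tol[j]]
      if (!length(cand)) {
        verified[test[j]] <- FALSE
        next
      }
      k <- cand[which.min(abs(pl$mz[cand] - sat_mz[j]))]
      expected <- C13_ABUNDANCE * assigned$C[test[j]] * assigned$intensity[test[j]]
      ratio <- pl$intensity[k] / expected
      verified[test[j]] <- ratio >= ratio_window[1] && ratio <= ratio_window[2]
    }
  }
  assigned$isotope_verified <- verified
  if (drop_unverified)
    assigned <- assigned[is.na(verified) | verified, , drop = FALSE]
  rownames(assigned) <- NULL
  assigned
}

#' Assign molecular formulas to a peak list
#'
#' Full per-measurement assignment chain: m/z range filter, method detection
#' limit, optional recalibration, candidate enumeration on the composition
#' grid, homologous-series resolution, 13C verification.
#'
#' @param pl A [peaklist()].
#' @param reference Optional calibration formulas for [recalibrate()].
#' @param tol_ppm Assignment tolerance in ppm (default 0.5).
#' @param grid Composition grid, see [formula_grid()].
#' @param mz_range Acquisition window (default c(50, 1000)).
#' @param ... Passed to [verify_isotopes()].
#' @return Assignment table: `mz`, `intensity`, count columns,
#'   `neutral_mass`, `error_ppm`, `formula`, `series_score`,
#'   `isotope_verified`; attributes `sample_id`, `replicate_id`, `mdl`.
#' @export
assign_peaklist <- function(pl, reference = NULL, tol_ppm = 0.5,
                            grid = formula_grid(), mz_range = c(50, 1000),
                            ...) {
  pl <- filter_mz_range(pl, mz_range)
  mdl <- estimate_mdl(pl)
  kept <- apply_mdl(pl, mdl)
  if (!is.null(reference))
    kept <- recalibrate(kept, reference)
  mono <- which(!flag_isotopologues(kept))
  neutral <- kept$mz[mono] + PROTON_MASS
  cand <- enumerate_candidates(neutral, tol_ppm = tol_ppm, grid = grid)
  cand <- cand[chemically_plausible(cand), , drop = FALSE]
  res <- resolve_by_series(cand, prior = reference)
  res$peak <- mono[res$peak]
  out <- data.frame(mz = kept$mz[res$peak], intensity = kept$intensity[res$peak],
                    res[, c(ELEMENTS, "neutral_mass", "error_ppm", "formula",
                            "series_score")])
  out <- verify_isotopes(out, kept, mdl, ...)
  attr(out, "sample_id") <- attr(pl, "sample_id")
  attr(out, "replicate_id") <- attr(pl, "replicate_id")
  attr(out, "mdl") <- mdl
  out
}
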