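# Independent oracles used to validate the fast implementations.

# Every grid composition with monoisotopic mass below `limit`, produced by
# plain nested enumeration over all eight elements -- deliberately
# independent of the package's closed-form C/H completion search.
brute_grid <- local({
  cache <- NULL
  function(limit = 400.5) {
    if (!is.null(cache)) return(cache)
    em <- element_masses()
    chunks <- list()
    for (N in 0:6) for (S in 0:2) for (P in 0:1) for (Cl in 0:2) for (Fe in 0:2) {
      base <- N * em[["N"]] + S * em[["S"]] + P * em[["P"]] +
        Cl * em[["Cl"]] + Fe * em[["Fe"]]
      if (base + em[["C"]] + em[["H"]] + em[["O"]] > limit) next
      for (O in 1:100) {
        m0 <- base + O * em[["O"]]
        if (m0 + em[["C"]] + em[["H"]] > limit) break
        for (C in 1:100) {
          m1 <- m0 + C * em[["C"]]
          if (m1 + em[["H"]] > limit) break
          hmax <- min(200L, floor((limit - m1) / em[["H"]]))
          H <- seq_len(hmax)
          chunks[[length(chunks) + 1L]] <- data.frame(
            C = C, H = H, N = N, O = O, S = S, P = P, Cl = Cl, Fe = Fe,
            mass = m1 + H * em[["H"]])
        }
      }
    }
    cache <<- do.call(rbind, chunks)
    cache
  }
})

# the banned heteroatom blocks written out literally
oracle_heteroatoms_ok <- function(N, S, P) {
  banned <- (N >= 1 & S >= 1 & P >= 1) |
    (N >= 2 & N <= 4 & S >= 1) |
    (N >= 2 & N <= 4 & P >= 1) |
    (N >= 1 & N <= 4 & S >= 2) |
    (S >= 2 & P >= 1) |
    ((N + S + P) >= 3 & !(S == 0 & P == 0 & N >= 3 & N <= 6))
  !banned
}

# reference candidate sets from the brute-force grid (sorted formula strings)
oracle_candidates <- function(mass, tol_ppm = 0.5) {
  g <- brute_grid()
  sel <- g[abs(g$mass - mass) < mass * tol_ppm * 1e-6, , drop = FALSE]
  sel <- sel[oracle_heteroatoms_ok(sel$N, sel$S, sel$P), , drop = FALSE]
  sort(unname(format_formula(sel)))
}

# O(N^2) pair sum for Rao's entropy
rao_bruteforce <- function(p, c) {
  p <- p / sum(p)
  n <- length(p)
  out <- 0
  for (i in seq_len(n - 1L))
    for (j in (i + 1L):n)
      out <- out + p[i] * p[j] * abs(c[i] - c[j])
  out
}
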