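# Molecular formula bookkeeping: count tables and text round-trip.
#
# Throughout the package a set of molecular formulas is a data.frame with
# integer columns C, H, N, O, S, P, Cl, Fe (one row per neutral composition).

#' Build a formula count table
#'
#' @param C,H,N,O,S,P,Cl,Fe Nonnegative integer atom counts (recycled).
#' @return data.frame with one row per formula and columns
#'   `C,H,N,O,S,P,Cl,Fe`.
#' @export
#' @examples
#' formula_table(C = 15, H = 14, O = 6)
formula_table <- function(C = 0L, H = 0L, N = 0L, O = 0L, S = 0L, P = 0L,
                          Cl = 0L, Fe = 0L) {
  ft <- data.frame(C = as.integer(C), H = as.integer(H), N = as.integer(N),
                   O = as.integer(O), S = as.integer(S), P = as.integer(P),
                   Cl = as.integer(Cl), Fe = as.integer(Fe))
  if (any(as.matrix(ft) < 0L, na.rm = TRUE))
    stop("atom counts must be nonnegative")
  ft
}

#' Parse molecular formula strings
#'
#' Accepts Hill-like strings such as `"C15H14O6"` or `"C20H23FeN3O2"`.
#' Parsing and [format_formula()] round-trip exactly.
#'
#' @param x Character vector of formula strings.
#' @return Formula count table (see [formula_table()]).
#' @export
#' @examples
#' parse_formula(c("C15H14O6", "CH4"))
parse_formula <- function(x) {
  x <- as.character(x)
  out <- matrix(0L, nrow = length(x), ncol = length(ELEMENTS),
                dimnames = list(NULL, ELEMENTS))
  for (i in seq_along(x)) {
    s <- x[i]
    if (is.na(s) || !nzchar(s)) {
      out[i, ] <- NA_integer_
      next
    }
    m <- gregexpr("([A-Z][a-z]?)([0-9]*)", s)[[1]]
    toks <- regmatches(s, gregexpr("([A-Z][a-z]?)([0-9]*)", s))[[1]]
    if (sum(nchar(toks)) != nchar(s))
      stop("cannot parse formula string: '", s, "'")
    for (tok in toks) {
      el <- sub("[0-9]*$", "", tok)
      n <- sub("^[A-Za-z]+", "", tok)
      if (!el %in% ELEMENTS)
        stop("unknown element '", el, "' in formula '", s, "'")
      out[i, el] <- out[i, el] + if (nzchar(n)) as.integer(n) else 1L
    }
  }
  as.data.frame(out)
}

#' Format formula count tables as text
#'
#' Inverse of [parse_formula()]: Hill-like order (C, H, then Cl, Fe, N, O,
#' P, S alphabetically), zero counts omitted, count one written without a
#' number.
#'
#' @param ft Formula count table.
#' @return Character vector of canonical formula strings.
#' @export
#' @examples
#' format_formula(formula_table(C = 20, H = 23, N = 3, O = 2, Fe = 1))
format_formula <- function(ft) {
  ft <- as_formula_table(ft)
  if (nrow(ft) == 0L) return(character(0))
  ord <- c("C", "H", sort(setdiff(ELEMENTS, c("C", "H"))))
  mat <- as.matrix(ft[, ord, drop = FALSE])
  apply(mat, 1L, function(cnt) {
    keep <- which(cnt > 0L)
    if (!length(keep)) return("")
    paste0(ord[keep], ifelse(cnt[keep] == 1L, "", cnt[keep]), collapse = "")
  })
}

# coerce anything formula-like (strings, count data.frame possibly with extra
# columns) to the canonical count table
as_formula_table <- function(x) {
  if (is.character(x)) return(parse_formula(x))
  if (is.data.frame(x) || is.matrix(x)) {
    x <- as.data.frame(x)
    missing <- setdiff(ELEMENTS, names(x))
    for (el in missing) x[[el]] <- 0L
    return(x[, ELEMENTS, drop = FALSE])
  }
  stop("cannot interpret object of class '", class(x)[1], "' as formulas")
}

# TRUE where a composition lies inside the assignment grid
within_grid <- function(ft, grid = formula_grid()) {
  ft <- as_formula_table(ft)
  ft$C >= grid$C[1] & ft$C <= grid$C[2] &
    ft$H >= grid$H[1] & ft$H <= grid$H[2] &
    ft$O >= grid$O[1] & ft$O <= grid$O[2] &
    ft$N >= grid$N[1] & ft$N <= grid$N[2] &
    ft$S >= grid$S[1] & ft$S <= grid$S[2] &
    ft$P >= grid$P[1] & ft$P <= grid$P[2] &
    ft$Cl >= grid$Cl[1] & ft$Cl <= grid$Cl[2] &
    ft$Fe >= grid$Fe[1] & ft$Fe <= grid$Fe[2]
}

#' Assignment composition grid
#'
#' Bounds of the candidate composition space searched during formula
#' assignment: C 1-100, H 1-200, O 1-100, N 0-6, S 0-2, P 0-1, Cl 0-2,
#' Fe 0-2.
#'
#' @param ... Name = `c(min, max)` overrides for individual elements.
#' @return Named list of length-2 integer ranges.
#' @export
formula_grid <- function(...) {
  grid <- list(C = c(1L, 100L), H = c(1L, 200L), O = c(1L, 100L),
               N = c(0L, 6L), S = c(0L, 2L), P = c(0L, 1L),
               Cl = c(0L, 2L), Fe = c(0L, 2L))
  dots <- list(...)
  for (nm in names(dots)) {
    if (!nm %in% names(grid)) stop("unknown grid element '", nm, "'")
    grid[[nm]] <- as.integer(dots[[nm]])
  }
  grid
}
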