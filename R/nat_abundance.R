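#' Default isotope abundance table
#'
#' Per-element mass-shift probabilities (shift 0, +1, +2, ...) from standard
#' IUPAC terrestrial abundances. Overridable entry by entry.
#'
#' @param overrides optional named list of probability vectors replacing the
#'   defaults (each must be nonnegative and sum to 1).
#' @return named list of numeric vectors, class `isotope_table`.
#' @export
isotope_table <- function(overrides = NULL) {
  tab <- list(
    C  = c(0.9893, 0.0107),
    H  = c(0.999885, 0.000115),
    N  = c(0.99636, 0.00364),
    O  = c(0.99757, 0.00038, 0.00205),
    Si = c(0.92223, 0.04685, 0.03092),
    S  = c(0.9499, 0.0075, 0.0425, 0.0, 0.0001)
  )
  if (!is.null(overrides)) {
    for (el in names(overrides)) tab[[el]] <- overrides[[el]]
  }
  for (el in names(tab)) {
    v <- tab[[el]]
    if (any(v < 0) || abs(sum(v) - 1) > 1e-6)
      stop("isotope table entry for ", el, " is not a probability vector")
  }
  structure(tab, class = "isotope_table")
}

#' Elemental formula of a measured fragment
#'
#' Splits the measured ion into the tracer-carrying backbone carbons and all
#' other atoms (backbone-adjacent plus derivatization atoms, e.g. the C, H
#' and Si added by TBDMS groups). Only the non-backbone atoms contribute the
#' fixed natural-abundance envelope; the unlabelled backbone carbons
#' contribute a residual 13C binomial that depends on how many are labelled.
#'
#' @param backbone_carbons number of tracer-capable carbons (MID length - 1).
#' @param ... element counts of all other atoms, e.g. `C = 6, H = 24, Si = 1`.
#' @return list of class `elemental_formula`.
#' @export
elemental_formula <- function(backbone_carbons, ...) {
  other <- list(...)
  if (length(other) == 1 && is.list(other[[1]]) && is.null(names(other)[1]))
    other <- other[[1]]
  backbone_carbons <- as.integer(backbone_carbons)
  stopifnot(backbone_carbons >= 1L)
  cnt <- vapply(other, as.numeric, numeric(1))
  if (length(cnt) && (is.null(names(cnt)) || any(names(cnt) == "")))
    stop("elemental_formula: all atom counts must be named by element")
  if (any(cnt < 0) || any(cnt != round(cnt)))
    stop("elemental_formula: atom counts must be nonnegative integers")
  structure(list(backbone_carbons = backbone_carbons,
                 other = as.list(cnt)), class = "elemental_formula")
}

conv_trunc <- function(a, b, len = length(a) + length(b) - 1L) {
  out <- numeric(len)
  for (i in seq_along(a)) {
    jmax <- min(length(b), len - i + 1L)
    if (jmax >= 1L)
      out[i:(i + jmax - 1L)] <- out[i:(i + jmax - 1L)] + a[i] * b[seq_len(jmax)]
  }
  out
}

#' Natural-abundance mass-shift envelope of the non-tracer atoms
#'
#' Convolves the per-atom isotope distributions of every atom outside the
#' tracer backbone into a single mass-shift probability vector.
#'
#' @param formula an `elemental_formula`.
#' @param isotopes an `isotope_table`.
#' @return numeric probability vector over mass shifts 0, 1, 2, ...
#' @export
abundance_vector <- function(formula, isotopes = isotope_table()) {
  stopifnot(inherits(formula, "elemental_formula"))
  vec <- 1
  for (el in names(formula$other)) {
    n <- formula$other[[el]]
    if (n == 0) next
    dist <- isotopes[[el]]
    if (is.null(dist)) stop("abundance_vector: unknown element '", el, "'")
    for (i in seq_len(n)) vec <- conv_trunc(vec, dist)
  }
  vec
}

#' Natural-abundance correction matrix
#'
#' Column `j+1` gives the measured mass-shift distribution of a molecule that
#' is truly m+j: the fixed envelope of the non-backbone atoms convolved with
#' the residual 13C binomial of the `backbone - j` unlabelled backbone
#' carbons, truncated to the measured window m+0..m+C. The matrix is lower
#' triangular with positive diagonal.
#'
#' @param formula an `elemental_formula`.
#' @param isotopes an `isotope_table`.
#' @return a `(C+1) x (C+1)` matrix.
#' @export
correction_matrix <- function(formula, isotopes = isotope_table()) {
  nb <- formula$backbone_carbons
  len <- nb + 1L
  p13 <- if (length(isotopes$C) >= 2) isotopes$C[2] / sum(isotopes$C) else 0
  env <- abundance_vector(formula, isotopes)
  M <- matrix(0, len, len)
  for (j in 0:nb) {
    resid <- stats::dbinom(0:(nb - j), nb - j, p13)
    col <- conv_trunc(env, resid)
    # shift by the true label count j, truncate to the measured window
    full <- numeric(len)
    kmax <- min(length(col), len - j)
    if (kmax >= 1L) full[(j + 1):(j + kmax)] <- col[seq_len(kmax)]
    M[, j + 1L] <- full
  }
  M
}

#' Forward-convolve a tracer MID with natural abundance
#'
#' Applies the correction matrix to a clean tracer-only MID to produce the
#' distribution an instrument reporting the m+0..m+C window would observe.
#' The truncated result is renormalized; the mass lost to truncation is
#' attached as the `"mass_loss"` attribute.
#'
#' @param mid numeric MID vector (m+0..m+C), summing to 1.
#' @param formula an `elemental_formula` with matching backbone.
#' @param isotopes an `isotope_table`.
#' @return the measured MID (sums to 1).
#' @export
convolve_mid <- function(mid, formula, isotopes = isotope_table()) {
  stopifnot(length(mid) == formula$backbone_carbons + 1L)
  if (any(mid < -1e-12) || abs(sum(mid) - 1) > 1e-6)
    stop("convolve_mid: input is not a valid MID")
  M <- correction_matrix(formula, isotopes)
  raw <- as.vector(M %*% mid)
  s <- sum(raw)
  out <- raw / s
  attr(out, "mass_loss") <- 1 - s
  out
}

#' Correct a measured MID for natural abundance
#'
#' Inverts the forward model by nonnegative least squares against the
#' lower-triangular correction matrix, then renormalizes. NNLS (rather than
#' plain matrix inversion) keeps noisy inputs from producing negative
#' fractions; any clamping performed by the solver is reported in the
#' `"n_clamped"` attribute. Satisfies
#' `correct_mid(convolve_mid(x)) == x` to solver precision.
#'
#' @param measured measured MID vector (m+0..m+C), summing to 1.
#' @param formula an `elemental_formula` with matching backbone.
#' @param isotopes an `isotope_table`.
#' @return the corrected tracer-only MID.
#' @export
correct_mid <- function(measured, formula, isotopes = isotope_table()) {
  stopifnot(length(measured) == formula$backbone_carbons + 1L)
  if (any(measured < -1e-9) || abs(sum(measured) - 1) > 1e-6)
    stop("correct_mid: input is not a valid MID")
  M <- correction_matrix(formula, isotopes)
  if (any(diag(M) <= 1e-12) || rcond(M) < 1e-12)
    stop("correct_mid: ill-conditioned correction matrix for formula with ",
         formula$backbone_carbons, " backbone carbons")
  fit <- pracma::lsqnonneg(M, as.numeric(measured))
  x <- fit$x
  unconstrained <- solve(M, as.numeric(measured))
  n_clamped <- sum(x == 0 & unconstrained < -1e-10)
  s <- sum(x)
  if (s <= 0) stop("correct_mid: degenerate solution (all-zero)")
  out <- x / s
  attr(out, "n_clamped") <- n_clamped
  out
}

#' TBDMS-derivatized fragment formulas for common TCA metabolites
#'
#' Convenience non-backbone formulas for tert-butyldimethylsilyl derivatives
#' of the metabolites measured by GC-MS in tracing studies. Each TBDMS group
#' adds C6H15Si (of which C6H14Si remain on the measured fragment after loss
#' of a methyl or butyl is ignored here); values are typical fragment
#' compositions and can be replaced per study.
#'
#' @param metabolite one of `"pyruvate"`, `"citrate"`, `"alpha_kg"`,
#'   `"succinate"`, `"fumarate"`, `"malate"`, `"glutamate"`, `"glutamine"`.
#' @return an `elemental_formula`.
#' @export
tbdms_formula <- function(metabolite) {
  specs <- list(
    pyruvate  = list(nb = 3L, C = 6,  H = 14, N = 1, O = 3, Si = 1),
    citrate   = list(nb = 6L, C = 14, H = 39, O = 7, Si = 3),
    alpha_kg  = list(nb = 5L, C = 9,  H = 24, N = 1, O = 5, Si = 2),
    succinate = list(nb = 4L, C = 8,  H = 23, O = 4, Si = 2),
    fumarate  = list(nb = 4L, C = 8,  H = 21, O = 4, Si = 2),
    malate    = list(nb = 4L, C = 11, H = 29, O = 5, Si = 3),
    glutamate = list(nb = 5L, C = 12, H = 32, N = 1, O = 4, Si = 3),
    glutamine = list(nb = 5L, C = 12, H = 33, N = 2, O = 3, Si = 3)
  )
  s <- specs[[tolower(metabolite)]]
  if (is.null(s)) stop("no fragment formula for metabolite: ", metabolite)
  elemental_formula(s$nb, s[setdiff(names(s), "nb")])
}
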