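#' Metabolite pools of the TCA-cycle model
#'
#' Carbon counts and symmetry flags for the pools tracked by the simulator.
#' Succinate and fumarate are symmetric: their positional distributions are
#' indistinguishable from the carbon-reversed distribution and the simulator
#' scrambles them accordingly.
#'
#' @format A data frame with columns `metabolite`, `n_carbons`, `symmetric`.
#' @export
tca_pools <- function() {
  data.frame(
    metabolite = c("pyruvate", "acetyl_coa", "oaa", "citrate", "alpha_kg",
                   "glutamate", "glutamine", "succinate", "fumarate", "malate"),
    n_carbons  = c(3L, 2L, 4L, 6L, 5L, 5L, 5L, 4L, 4L, 4L),
    symmetric  = c(FALSE, FALSE, FALSE, FALSE, FALSE,
                   FALSE, FALSE, TRUE, TRUE, FALSE),
    stringsAsFactors = FALSE
  )
}

pool_carbons <- function(metabolite) {
  p <- tca_pools()
  i <- match(tolower(metabolite), p$metabolite)
  if (is.na(i)) stop("unknown metabolite pool: ", metabolite)
  p$n_carbons[i]
}

#' Construct a positional labelling state
#'
#' A positional state is a probability distribution over the `2^n` binary
#' carbon-labelling patterns of one metabolite pool. Pattern index `k`
#' (0-based) has carbon `i` labelled iff bit `i-1` of `k` is set.
#'
#' @param n_carbons number of backbone carbons (>= 1).
#' @param probs numeric vector of length `2^n_carbons`, nonnegative, summing
#'   to 1 within `1e-9`.
#' @param metabolite optional pool name.
#' @return an object of class `positional_state`.
#' @export
positional_state <- function(n_carbons, probs, metabolite = NA_character_) {
  n_carbons <- as.integer(n_carbons)
  stopifnot(n_carbons >= 1L, length(probs) == 2^n_carbons)
  if (any(probs < -1e-12)) stop("positional state has negative entries")
  probs <- pmax(probs, 0)
  s <- sum(probs)
  if (abs(s - 1) > 1e-9) stop("positional state does not sum to 1 (sum = ", s, ")")
  structure(list(metabolite = metabolite, n_carbons = n_carbons, probs = probs / s),
            class = "positional_state")
}

#' Point-mass positional state
#'
#' @param n_carbons number of carbons.
#' @param labelled integer vector of labelled carbon positions (1-based);
#'   empty for the fully unlabelled state.
#' @param metabolite optional pool name.
#' @export
ps_delta <- function(n_carbons, labelled = integer(0), metabolite = NA_character_) {
  stopifnot(all(labelled >= 1), all(labelled <= n_carbons))
  probs <- numeric(2^n_carbons)
  probs[sum(2^(labelled - 1)) + 1] <- 1
  positional_state(n_carbons, probs, metabolite)
}

#' @export
print.positional_state <- function(x, ...) {
  cat("<positional_state>", if (!is.na(x$metabolite)) x$metabolite else "",
      sprintf("(%d carbons, %d patterns)\n", x$n_carbons, length(x$probs)))
  nz <- which(x$probs > 1e-12)
  for (k in nz) {
    bits <- which(bitwAnd(bitwShiftR(k - 1L, 0:(x$n_carbons - 1L)), 1L) == 1L)
    cat(sprintf("  {%s}: %.6g\n", paste(bits, collapse = ","), x$probs[k]))
  }
  invisible(x)
}

#' Apply a carbon atom map to a positional state
#'
#' Builds the downstream pool from an upstream one. `map[j]` names the source
#' carbon that becomes target carbon `j`; `0` introduces a new, unlabelled
#' carbon (e.g. CO2 fixation). Source carbons absent from `map` are released
#' (marginalized out), e.g. as CO2.
#'
#' @param state a `positional_state`.
#' @param map integer vector, one entry per target carbon.
#' @param metabolite name for the product pool.
#' @return the product `positional_state`.
#' @export
ps_map <- function(state, map, metabolite = NA_character_) {
  stopifnot(inherits(state, "positional_state"))
  map <- as.integer(map)
  if (any(map < 0L) || any(map > state$n_carbons))
    stop("atom map refers to carbons outside the source pool")
  n_out <- length(map)
  src <- 0:(2^state$n_carbons - 1L)
  tidx <- integer(length(src))
  for (j in seq_len(n_out)) {
    if (map[j] > 0L)
      tidx <- tidx + bitwShiftL(bitwAnd(bitwShiftR(src, map[j] - 1L), 1L), j - 1L)
  }
  out <- numeric(2^n_out)
  agg <- rowsum(state$probs, tidx)
  out[as.integer(rownames(agg)) + 1L] <- agg[, 1L]
  positional_state(n_out, out, metabolite)
}

#' Symmetry scrambling at succinate/fumarate
#'
#' Averages a positional distribution with its carbon reversal, modelling the
#' loss of positional information at the symmetric intermediates.
#'
#' @param state a `positional_state`.
#' @return the scrambled `positional_state`.
#' @export
ps_scramble <- function(state) {
  rev_state <- ps_map(state, rev(seq_len(state$n_carbons)), state$metabolite)
  positional_state(state$n_carbons, (state$probs + rev_state$probs) / 2, state$metabolite)
}

#' Mix positional states
#'
#' Convex combination of positional states of the same pool size.
#'
#' @param states list of `positional_state` objects.
#' @param weights nonnegative weights summing to 1.
#' @param metabolite name for the mixture.
#' @export
ps_mix <- function(states, weights, metabolite = NA_character_) {
  stopifnot(length(states) == length(weights), all(weights >= -1e-12))
  weights <- pmax(weights, 0)
  if (abs(sum(weights) - 1) > 1e-9) stop("mixture weights must sum to 1")
  n <- states[[1]]$n_carbons
  probs <- numeric(2^n)
  for (i in seq_along(states)) {
    if (states[[i]]$n_carbons != n) stop("mixture over pools of unequal size")
    probs <- probs + weights[i] * states[[i]]$probs
  }
  positional_state(n, probs, metabolite)
}

#' Citrate-synthase condensation
#'
#' Joins an oxaloacetate state (4 carbons) with an acetyl unit (2 carbons)
#' into citrate (6 carbons): citrate carbons 1-4 are the OAA carbons, 5-6 the
#' acetyl carbons. The two pools condense independently, so the citrate
#' pattern distribution is the product distribution; expected label counts
#' add.
#'
#' @param oaa 4-carbon `positional_state`.
#' @param acetyl 2-carbon `positional_state`.
#' @return citrate `positional_state` (6 carbons).
#' @export
condense <- function(oaa, acetyl) {
  stopifnot(inherits(oaa, "positional_state"), inherits(acetyl, "positional_state"))
  if (oaa$n_carbons != 4L) stop("condense: OAA pool must have 4 carbons, got ", oaa$n_carbons)
  if (acetyl$n_carbons != 2L) stop("condense: acetyl pool must have 2 carbons, got ", acetyl$n_carbons)
  # column-major stacking puts OAA in the low 4 bits, acetyl in bits 5-6
  positional_state(6L, as.vector(outer(oaa$probs, acetyl$probs)), "citrate")
}

#' Collapse a positional state to its mass isotopologue distribution
#'
#' @param state a `positional_state`.
#' @return numeric vector of length `n_carbons + 1`; entry `k+1` is the total
#'   probability of patterns with exactly `k` labelled carbons (m+k).
#' @export
positional_to_mid <- function(state) {
  stopifnot(inherits(state, "positional_state"))
  n <- state$n_carbons
  idx <- 0:(2^n - 1L)
  pops <- integer(length(idx))
  for (b in 0:(n - 1L)) pops <- pops + bitwAnd(bitwShiftR(idx, b), 1L)
  mid <- numeric(n + 1L)
  agg <- rowsum(state$probs, pops)
  mid[as.integer(rownames(agg)) + 1L] <- agg[, 1L]
  mid
}

#' Expected number of labelled carbons
#'
#' @param state a `positional_state`.
#' @export
expected_labels <- function(state) {
  sum(positional_to_mid(state) * 0:state$n_carbons)
}
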