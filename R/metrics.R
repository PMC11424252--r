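#' Total isotopologue labelling
#'
#' The fraction of molecules carrying at least one tracer carbon,
#' `1 - (m+0)`. This metric integrates all routes of label entry and all
#' turns of the cycle.
#'
#' @param mid numeric MID vector (m+0..m+C).
#' @return scalar in `[0, 1]`.
#' @export
total_labelling <- function(mid) {
  if (any(mid < -1e-9) || abs(sum(mid) - 1) > 1e-6)
    stop("total_labelling: input is not a valid MID")
  1 - mid[1]
}

missing_value <- function(reason) {
  structure(NA_real_, reason = reason)
}

mid_fraction <- function(mids, metabolite, shift) {
  m <- mids[[tolower(metabolite)]]
  if (is.null(m)) return(NULL)
  if (shift + 1L > length(m)) return(NULL)
  m[shift + 1L]
}

#' Isotopologue ratio metric
#'
#' Plain ratio of two isotopologue fractions, e.g. citrate m+2 / pyruvate
#' m+3 (glucose contribution through PDH) or citrate m+4 / citrate m+2
#' (label retention through two turns). A denominator at or below `tol`
#' yields a missing value carrying a reason code instead of an error, so
#' cohort tables stay rectangular.
#'
#' @param mids named list of MID vectors (names matched case-insensitively).
#' @param numerator,denominator `(metabolite, shift)` pairs, e.g.
#'   `c("citrate", 2)`.
#' @param tol denominators at or below this are treated as missing.
#' @return scalar ratio, or `NA` with a `"reason"` attribute.
#' @export
ratio_metric <- function(mids, numerator, denominator, tol = 1e-9) {
  num <- mid_fraction(mids, numerator[[1]], as.integer(numerator[[2]]))
  den <- mid_fraction(mids, denominator[[1]], as.integer(denominator[[2]]))
  if (is.null(num) || is.null(den))
    return(missing_value("isotopologue not present in record"))
  if (den <= tol) return(missing_value("denominator below tolerance"))
  num / den
}

#' Normalize tissue labelling to plasma enrichment
#'
#' Divides a tissue total-labelling value by a plasma isotopologue fraction
#' (glucose m+6 or pyruvate m+3), removing differences in delivered tracer.
#'
#' @param total tissue total labelling (scalar).
#' @param plasma_mid plasma MID vector.
#' @param shift isotopologue shift of the plasma reference (e.g. 6 for
#'   glucose m+6).
#' @param tol missing-value threshold for the plasma fraction.
#' @return scalar, or `NA` with a reason attribute.
#' @export
normalize_to_plasma <- function(total, plasma_mid, shift, tol = 1e-9) {
  p <- plasma_mid[shift + 1L]
  if (is.na(p) || p <= tol) return(missing_value("plasma fraction below tolerance"))
  total / p
}

#' Fraction of glutamate labelling carried by the [4,5-13C] isotopomer
#'
#' First-turn metabolism of [1,2-13C]acetyl-CoA places both tracer carbons
#' on glutamate carbons 4 and 5; later turns spread label to other
#' positions. The fraction of labelled glutamate in exactly the `{4,5}`
#' pattern therefore reports the ratio of first-turn to multi-turn cycling.
#'
#' @param state a 5-carbon glutamate `positional_state`.
#' @return scalar in `[0, 1]`; `NA` (reason-coded) if fully unlabelled.
#' @export
glu45_fraction <- function(state) {
  stopifnot(inherits(state, "positional_state"))
  if (state$n_carbons != 5L) stop("glu45_fraction: glutamate state must have 5 carbons")
  p_unlab <- state$probs[1]
  labelled <- 1 - p_unlab
  if (labelled <= 1e-12) return(missing_value("glutamate fully unlabelled"))
  p45 <- state$probs[sum(2^(c(4, 5) - 1)) + 1]
  p45 / labelled
}

#' Respiratory control ratio
#'
#' Ratio of ADP-stimulated (state III) to ADP-unstimulated (state IV)
#' oxygen consumption of isolated mitochondria; values well above 1 indicate
#' coupled respiration.
#'
#' @param state3 state III OCR (pmol O2/min), positive.
#' @param state4 state IV OCR (pmol O2/min), positive.
#' @return scalar ratio (vectorized).
#' @export
respiratory_control_ratio <- function(state3, state4) {
  if (any(state3 <= 0) || any(state4 <= 0))
    stop("respiratory_control_ratio: OCR values must be positive")
  state3 / state4
}

#' Standard labelling metrics for a fragment cohort
#'
#' Computes, per tissue fragment, the metrics used to compare tumour and
#' kidney labelling: citrate m+2 / pyruvate m+3, citrate m+4 / citrate m+2,
#' total labelling (1 - m+0) of each TCA intermediate, citrate m+5 and
#' malate m+3 fractional enrichments, and (when positional glutamate data
#' are present) the [4,5-13C]glutamate fraction.
#'
#' @param cohort a tracing cohort as produced by [generate_tracing_cohort()]
#'   or read by [read_mid_table()]: a list with a long-format `mids` data
#'   frame (patient, fragment, tissue, metabolite, isotopologue, fraction)
#'   and optionally a `glu45` data frame.
#' @return long-format data frame (patient, fragment, tissue, metric, value).
#' @export
fragment_metrics <- function(cohort) {
  mids_df <- cohort$mids
  keys <- unique(mids_df[, c("patient", "fragment", "tissue")])
  rows <- list()
  for (i in seq_len(nrow(keys))) {
    sub <- mids_df[mids_df$patient == keys$patient[i] &
                   mids_df$fragment == keys$fragment[i], ]
    mids <- split(sub$fraction[order(sub$isotopologue)],
                  sub$metabolite[order(sub$isotopologue)])
    mids <- lapply(mids, as.numeric)
    names(mids) <- tolower(names(mids))
    vals <- c(
      cit_m2_over_pyr_m3 = as.numeric(ratio_metric(mids, c("citrate", 2), c("pyruvate", 3))),
      cit_m4_over_cit_m2 = as.numeric(ratio_metric(mids, c("citrate", 4), c("citrate", 2))),
      citrate_m5 = if (!is.null(mids$citrate)) mids$citrate[6] else NA_real_,
      malate_m3 = if (!is.null(mids$malate)) mids$malate[4] else NA_real_
    )
    for (m in intersect(c("citrate", "malate", "succinate", "fumarate", "glutamate"),
                        names(mids)))
      vals[paste0("total_labelling_", m)] <- total_labelling(mids[[m]])
    rows[[i]] <- data.frame(patient = keys$patient[i], fragment = keys$fragment[i],
                            tissue = keys$tissue[i], metric = names(vals),
                            value = unname(vals), stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  if (!is.null(cohort$glu45)) {
    g <- cohort$glu45
    out <- rbind(out, data.frame(patient = g$patient, fragment = g$fragment,
                                 tissue = g$tissue, metric = "glu45_fraction",
                                 value = g$value, stringsAsFactors = FALSE))
  }
  rownames(out) <- NULL
  out
}
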