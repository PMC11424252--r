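#' Metabolomics feature table
#'
#' Container for an intensity matrix with sample and feature metadata, the
#' substrate of the QC/normalization pipeline.
#'
#' @param intensities numeric matrix, features x samples, nonnegative.
#' @param samples data frame with columns `sample`, `run_order` (integer,
#'   unique within batch), `type` (`study`, `QC` or `blank`) and optionally
#'   `batch`.
#' @param features data frame with columns `feature`, `mode` (`positive` or
#'   `negative`) and optionally `hmdb` (identity used for mode
#'   deduplication and cross-study matching).
#' @return object of class `feature_table`.
#' @export
feature_table <- function(intensities, samples, features = NULL) {
  intensities <- as.matrix(intensities)
  stopifnot(is.numeric(intensities), ncol(intensities) == nrow(samples))
  if (any(intensities < 0)) stop("feature_table: intensities must be nonnegative")
  req <- c("sample", "run_order", "type")
  if (!all(req %in% names(samples)))
    stop("feature_table: sample sheet needs columns ", paste(req, collapse = ", "))
  if (!all(samples$type %in% c("study", "QC", "blank")))
    stop("feature_table: sample type must be study, QC or blank")
  if (is.null(samples$batch)) samples$batch <- 1L
  if (anyDuplicated(samples[, c("batch", "run_order")]))
    stop("feature_table: run orders must be unique within batch")
  if (is.null(features)) {
    features <- data.frame(feature = rownames(intensities) %||%
                             paste0("F", seq_len(nrow(intensities))),
                           mode = "positive", stringsAsFactors = FALSE)
  }
  stopifnot(nrow(features) == nrow(intensities))
  if (is.null(features$mode)) features$mode <- "positive"
  if (is.null(features$hmdb)) features$hmdb <- features$feature
  rownames(intensities) <- features$feature
  colnames(intensities) <- samples$sample
  structure(list(intensities = intensities, samples = samples, features = features),
            class = "feature_table")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.feature_table <- function(x, ...) {
  cat(sprintf("<feature_table> %d features x %d samples (%d study, %d QC, %d blank)\n",
              nrow(x$intensities), ncol(x$intensities),
              sum(x$samples$type == "study"), sum(x$samples$type == "QC"),
              sum(x$samples$type == "blank")))
  invisible(x)
}

#' QC pipeline configuration
#'
#' Thresholds of the QC/normalization pipeline. The defaults are common
#' practice values for LC/GC-MS feature tables.
#'
#' @param snr_min minimum signal-to-noise (QC median / blank median) to keep
#'   a feature.
#' @param bh_alpha BH-adjusted significance level of the run-order trend
#'   test gating the LOESS correction.
#' @param loess_span span of the LOESS fit of QC intensity on run order.
#' @param stable_cv_max maximum QC coefficient of variation for a feature to
#'   join the normalization ("stable") subset.
#' @param stable_snr_min minimum signal-to-noise for the stable subset.
#' @param log_base base of the final log transformation.
#' @export
qc_config <- function(snr_min = 3, bh_alpha = 0.05, loess_span = 0.75,
                      stable_cv_max = 0.2, stable_snr_min = 10, log_base = 10) {
  cfg <- list(snr_min = snr_min, bh_alpha = bh_alpha, loess_span = loess_span,
              stable_cv_max = stable_cv_max, stable_snr_min = stable_snr_min,
              log_base = log_base)
  if (any(unlist(cfg) <= 0)) stop("qc_config: all thresholds must be positive")
  if (bh_alpha >= 1) stop("qc_config: bh_alpha must lie in (0, 1)")
  structure(cfg, class = "qc_config")
}

#' Per-feature signal-to-noise ratio
#'
#' Median intensity across QC samples divided by the median across blanks.
#' An all-zero blank median yields infinite S/N with a flag; the feature is
#' retained.
#'
#' @param ft a `feature_table` with at least one QC and one blank sample.
#' @return data frame with columns `feature`, `snr`, `infinite`.
#' @export
snr <- function(ft) {
  stopifnot(inherits(ft, "feature_table"))
  qc <- ft$intensities[, ft$samples$type == "QC", drop = FALSE]
  bl <- ft$intensities[, ft$samples$type == "blank", drop = FALSE]
  if (ncol(qc) < 1 || ncol(bl) < 1)
    stop("snr: the table must contain at least one QC and one blank sample")
  qmed <- apply(qc, 1, stats::median)
  bmed <- apply(bl, 1, stats::median)
  s <- ifelse(bmed > 0, qmed / bmed, Inf)
  data.frame(feature = ft$features$feature, snr = s, infinite = bmed == 0,
             stringsAsFactors = FALSE)
}

#' Run-order trend test on QC samples
#'
#' Per-feature Spearman correlation of QC intensity with run order, with
#' Benjamini-Hochberg adjustment across features. Following standard QC
#' practice, only the QC intensities inside the feature's interquartile
#' range enter the significance test, so single outlier injections do not
#' trigger a correction.
#'
#' @param ft a `feature_table` with >= 4 QC samples.
#' @param iqr_restrict restrict the test to QC points within the IQR
#'   (default `TRUE`).
#' @return data frame with columns `feature`, `rho`, `p`, `p_adj`,
#'   `n_used`.
#' @export
run_order_test <- function(ft, iqr_restrict = TRUE) {
  stopifnot(inherits(ft, "feature_table"))
  is_qc <- ft$samples$type == "QC"
  if (sum(is_qc) < 4) stop("run_order_test: need at least 4 QC samples")
  ro <- ft$samples$run_order[is_qc]
  qc <- ft$intensities[, is_qc, drop = FALSE]
  res <- lapply(seq_len(nrow(qc)), function(i) {
    y <- qc[i, ]
    keep <- rep(TRUE, length(y))
    if (iqr_restrict) {
      q <- stats::quantile(y, c(0.25, 0.75), names = FALSE)
      keep <- y >= q[1] & y <= q[2]
      if (sum(keep) < 4) keep <- rep(TRUE, length(y))
    }
    yy <- y[keep]; rr <- ro[keep]
    if (stats::sd(yy) == 0 || stats::sd(rr) == 0)
      return(c(rho = NA_real_, p = NA_real_, n = sum(keep)))
    ct <- suppressWarnings(stats::cor.test(rr, yy, method = "spearman"))
    c(rho = unname(ct$estimate), p = ct$p.value, n = sum(keep))
  })
  res <- do.call(rbind, res)
  data.frame(feature = ft$features$feature, rho = res[, "rho"], p = res[, "p"],
             p_adj = stats::p.adjust(res[, "p"], method = "BH"),
             n_used = res[, "n"], stringsAsFactors = FALSE)
}

#' LOESS run-order drift correction
#'
#' For every feature whose QC run-order trend is significant after BH
#' adjustment, fits a LOESS of QC intensity on run order and divides each
#' sample's intensity by the fitted trend at its run order, rescaled to the
#' QC median so corrected intensities keep their original scale. Features
#' without a significant trend pass through unchanged; features whose
#' fitted trend is nonpositive anywhere are skipped with a logged reason.
#'
#' @param ft a `feature_table`.
#' @param trend result of [run_order_test()] (computed if `NULL`).
#' @param config a `qc_config`.
#' @return corrected `feature_table`; the features corrected/skipped are in
#'   the `"qc_log"` attribute.
#' @export
loess_drift_correct <- function(ft, trend = NULL, config = qc_config()) {
  stopifnot(inherits(ft, "feature_table"))
  if (is.null(trend)) trend <- run_order_test(ft)
  is_qc <- ft$samples$type == "QC"
  ro_qc <- ft$samples$run_order[is_qc]
  ro_all <- ft$samples$run_order
  corrected <- character(0); skipped <- character(0)
  M <- ft$intensities
  for (i in seq_len(nrow(M))) {
    padj <- trend$p_adj[i]
    if (is.na(padj) || padj > config$bh_alpha) next
    y <- M[i, is_qc]
    fit <- stats::loess(y ~ ro_qc, span = config$loess_span,
                        degree = 1, family = "gaussian",
                        control = stats::loess.control(surface = "direct"))
    pred <- stats::predict(fit, newdata = data.frame(ro_qc = ro_all))
    # hold the fit flat beyond the QC-covered run-order range
    pred[ro_all < min(ro_qc)] <- stats::predict(fit, data.frame(ro_qc = min(ro_qc)))
    pred[ro_all > max(ro_qc)] <- stats::predict(fit, data.frame(ro_qc = max(ro_qc)))
    if (any(!is.finite(pred)) || any(pred <= 0)) {
      skipped <- c(skipped, ft$features$feature[i])
      next
    }
    M[i, ] <- M[i, ] / pred * stats::median(y)
    corrected <- c(corrected, ft$features$feature[i])
  }
  out <- feature_table(M, ft$samples, ft$features)
  attr(out, "qc_log") <- list(loess_corrected = corrected, loess_skipped = skipped)
  out
}

#' Total-ion-count normalization over a stable feature subset
#'
#' Selects the stable features (QC coefficient of variation at most
#' `stable_cv_max` and signal-to-noise at least `stable_snr_min`), computes
#' a per-sample factor as the median intensity of the stable subset divided
#' by the grand median of those medians, and divides every intensity by its
#' sample factor.
#'
#' @param ft a `feature_table`.
#' @param config a `qc_config`.
#' @param snr_table optional precomputed [snr()] result.
#' @return list with `table` (normalized `feature_table`), `factors`
#'   (per-sample factors) and `stable_features`.
#' @export
tic_normalize <- function(ft, config = qc_config(), snr_table = NULL) {
  stopifnot(inherits(ft, "feature_table"))
  if (is.null(snr_table)) snr_table <- snr(ft)
  qc <- ft$intensities[, ft$samples$type == "QC", drop = FALSE]
  cv <- apply(qc, 1, function(x) if (mean(x) > 0) stats::sd(x) / mean(x) else Inf)
  stable <- cv <= config$stable_cv_max & snr_table$snr >= config$stable_snr_min
  if (!any(stable))
    stop("tic_normalize: no stable features at stable_cv_max = ",
         config$stable_cv_max, ", stable_snr_min = ", config$stable_snr_min)
  med <- apply(ft$intensities[stable, , drop = FALSE], 2, stats::median)
  factors <- med / stats::median(med)
  M <- sweep(ft$intensities, 2, factors, "/")
  list(table = feature_table(M, ft$samples, ft$features),
       factors = stats::setNames(factors, ft$samples$sample),
       stable_features = ft$features$feature[stable])
}

#' Log transformation and ionization-mode deduplication
#'
#' Applies a log10 (or `log_base`) transformation after imputing zeros with
#' half the smallest positive value of the feature, then, for identities
#' measured in both positive and negative mode, keeps the measurement with
#' the higher signal-to-noise ratio (ties keep the positive mode, logged).
#'
#' @param ft a `feature_table`.
#' @param snr_table optional precomputed [snr()] result.
#' @param config a `qc_config`.
#' @return deduplicated, log-scale `feature_table`; imputations and tie
#'   breaks are recorded in the `"qc_log"` attribute.
#' @export
log_transform_and_dedupe <- function(ft, snr_table = NULL, config = qc_config()) {
  stopifnot(inherits(ft, "feature_table"))
  if (is.null(snr_table)) snr_table <- snr(ft)
  M <- ft$intensities
  imputed <- character(0)
  for (i in seq_len(nrow(M))) {
    z <- M[i, ] <= 0
    if (any(z)) {
      pos <- M[i, !z]
      if (!length(pos)) stop("log_transform_and_dedupe: feature ",
                             ft$features$feature[i], " is all-zero")
      M[i, z] <- min(pos) / 2
      imputed <- c(imputed, ft$features$feature[i])
    }
  }
  M <- log(M, base = config$log_base)
  id <- ft$features$hmdb
  keep <- rep(TRUE, nrow(M)); ties <- character(0)
  for (u in unique(id[duplicated(id)])) {
    rows <- which(id == u)
    s <- snr_table$snr[rows]
    best <- rows[which.max(s)]
    if (sum(s == max(s)) > 1) {
      pos_rows <- rows[s == max(s) & ft$features$mode[rows] == "positive"]
      if (length(pos_rows)) best <- pos_rows[1]
      ties <- c(ties, u)
    }
    keep[setdiff(rows, best)] <- FALSE
  }
  # log-scale values may be negative, so bypass the nonnegativity check
  out <- structure(list(intensities = M[keep, , drop = FALSE],
                        samples = ft$samples,
                        features = ft$features[keep, , drop = FALSE]),
                   class = "feature_table")
  attr(out, "qc_log") <- list(zero_imputed = imputed, snr_ties = ties)
  out
}

#' Cohen's d effect size
#'
#' Standardized mean difference `(mean(x) - mean(y)) / pooled SD`.
#'
#' @param x,y numeric vectors (>= 2 values each).
#' @return scalar; `NA` (reason-coded) when the pooled SD is zero.
#' @export
cohen_d <- function(x, y) {
  x <- x[is.finite(x)]; y <- y[is.finite(y)]
  if (length(x) < 2 || length(y) < 2)
    stop("cohen_d: both groups need at least 2 observations")
  sp <- sqrt(((length(x) - 1) * stats::var(x) + (length(y) - 1) * stats::var(y)) /
             (length(x) + length(y) - 2))
  if (sp == 0) return(missing_value("zero pooled SD"))
  (mean(x) - mean(y)) / sp
}

#' Per-metabolite effect sizes and cross-study concordance
#'
#' Min-normalizes each metabolite to the smallest observed value across the
#' dataset, log10-transforms, computes Cohen's d between tumour and normal
#' samples, and correlates the effect sizes with an external study over the
#' intersection of HMDB identifiers (Pearson).
#'
#' @param intensities matrix of raw intensities, features x samples.
#' @param is_tumour logical vector over samples.
#' @param hmdb HMDB identifiers per feature.
#' @param external optional data frame with columns `hmdb` and `d` from
#'   another study.
#' @return list with `effects` (data frame hmdb, d) and, when `external`
#'   is supplied, `correlation` and `n_matched`.
#' @export
effect_sizes_and_crossstudy <- function(intensities, is_tumour, hmdb,
                                        external = NULL) {
  intensities <- as.matrix(intensities)
  stopifnot(length(is_tumour) == ncol(intensities),
            length(hmdb) == nrow(intensities))
  if (sum(is_tumour) < 2 || sum(!is_tumour) < 2)
    stop("effect_sizes_and_crossstudy: need >= 2 samples per group")
  minval <- min(intensities[intensities > 0])
  L <- log10(pmax(intensities, minval) / minval)
  d <- vapply(seq_len(nrow(L)), function(i)
    as.numeric(cohen_d(L[i, is_tumour], L[i, !is_tumour])), numeric(1))
  effects <- data.frame(hmdb = hmdb, d = d, stringsAsFactors = FALSE)
  out <- list(effects = effects)
  if (!is.null(external)) {
    m <- merge(effects, external, by = "hmdb", suffixes = c("", "_ext"))
    m <- m[is.finite(m$d) & is.finite(m$d_ext), ]
    if (nrow(m) < 3) stop("effect_sizes_and_crossstudy: fewer than 3 matched ids")
    out$correlation <- stats::cor(m$d, m$d_ext, method = "pearson")
    out$n_matched <- nrow(m)
  }
  out
}

#' Run the full QC/normalization pipeline
#'
#' Fixed stage order: signal-to-noise filtering, run-order trend test,
#' conditional LOESS drift correction, TIC normalization over the stable
#' subset, log transformation and mode deduplication.
#'
#' @param ft a `feature_table`.
#' @param config a `qc_config`.
#' @return list with the processed `table` and a `report` describing every
#'   stage (features dropped, corrected, skipped, factors, imputations).
#' @export
run_qc_pipeline <- function(ft, config = qc_config()) {
  s0 <- snr(ft)
  keep <- s0$snr >= config$snr_min
  dropped <- ft$features$feature[!keep]
  ft1 <- feature_table(ft$intensities[keep, , drop = FALSE],
                       ft$samples, ft$features[keep, , drop = FALSE])
  s1 <- s0[keep, , drop = FALSE]
  trend <- run_order_test(ft1)
  ft2 <- loess_drift_correct(ft1, trend, config)
  loess_log <- attr(ft2, "qc_log")
  norm <- tic_normalize(ft2, config, snr_table = s1)
  ft3 <- log_transform_and_dedupe(norm$table, snr_table = s1, config = config)
  dedupe_log <- attr(ft3, "qc_log")
  list(table = ft3,
       report = list(snr = s0,
                     snr_dropped = dropped,
                     run_order = trend,
                     loess = loess_log,
                     tic_factors = norm$factors,
                     stable_features = norm$stable_features,
                     dedupe = dedupe_log))
}
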