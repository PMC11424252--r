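#' Read and write long-format MID tables
#'
#' The canonical interchange format is a long CSV with columns `patient`,
#' `fragment`, `tissue`, `metabolite`, `isotopologue`, `fraction`. On read,
#' each (fragment, metabolite) MID must sum to 1; sums off by at most
#' `1e-6` are renormalized, larger deviations are rejected naming the
#' offending fragment and metabolite.
#'
#' @param path file path.
#' @param tissues controlled tissue vocabulary; set to `NULL` to skip the
#'   check.
#' @return for `read_mid_table`, a list with element `mids` (validated long
#'   data frame) compatible with [fragment_metrics()].
#' @export
read_mid_table <- function(path,
                           tissues = c("adjacent_kidney", "ccRCC", "papillary",
                                       "chromophobe", "oncocytoma",
                                       "FH_deficient")) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  req <- c("patient", "fragment", "tissue", "metabolite", "isotopologue", "fraction")
  miss <- setdiff(req, names(df))
  if (length(miss)) stop("read_mid_table: missing columns: ", paste(miss, collapse = ", "))
  if (!is.null(tissues)) {
    bad <- !(df$tissue %in% tissues | grepl("^metastasis:", df$tissue))
    if (any(bad))
      stop("read_mid_table: unknown tissue class at rows ",
           paste(utils::head(which(bad), 5), collapse = ", "))
  }
  key <- paste(df$fragment, df$metabolite, sep = "\r")
  for (k in unique(key)) {
    idx <- which(key == k)
    s <- sum(df$fraction[idx])
    if (abs(s - 1) > 1e-6)
      stop("read_mid_table: fractions for fragment ", df$fragment[idx[1]],
           " metabolite ", df$metabolite[idx[1]], " sum to ", signif(s, 6))
    if (any(df$fraction[idx] < -1e-9))
      stop("read_mid_table: negative fraction for fragment ", df$fragment[idx[1]])
    df$fraction[idx] <- df$fraction[idx] / s
  }
  list(mids = df)
}

#' @rdname read_mid_table
#' @param cohort a cohort list with a `mids` data frame.
#' @export
write_mid_table <- function(cohort, path) {
  df <- if (is.data.frame(cohort)) cohort else cohort$mids
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a feature table from a wide CSV plus sample sheet
#'
#' @param table_path wide CSV: first columns `feature`, `mode`, `hmdb`
#'   (mode/hmdb optional), remaining columns one per sample.
#' @param samples_path CSV with columns `sample`, `run_order`, `type` and
#'   optionally `batch`.
#' @return a `feature_table`.
#' @export
read_feature_table <- function(table_path, samples_path) {
  tab <- utils::read.csv(table_path, stringsAsFactors = FALSE, check.names = FALSE)
  samples <- utils::read.csv(samples_path, stringsAsFactors = FALSE)
  meta_cols <- intersect(c("feature", "mode", "hmdb"), names(tab))
  if (!"feature" %in% meta_cols) stop("read_feature_table: need a 'feature' column")
  M <- as.matrix(tab[, setdiff(names(tab), meta_cols), drop = FALSE])
  feats <- tab[, meta_cols, drop = FALSE]
  M <- M[, samples$sample, drop = FALSE]
  feature_table(M, samples, feats)
}

#' @rdname read_feature_table
#' @param ft a `feature_table`.
#' @param out_prefix path prefix; writes `<prefix>_table.csv` and
#'   `<prefix>_samples.csv`.
#' @export
write_feature_table <- function(ft, out_prefix) {
  tab <- cbind(ft$features[, intersect(c("feature", "mode", "hmdb"), names(ft$features)),
                           drop = FALSE],
               as.data.frame(ft$intensities))
  utils::write.csv(tab, paste0(out_prefix, "_table.csv"), row.names = FALSE, quote = FALSE)
  utils::write.csv(ft$samples, paste0(out_prefix, "_samples.csv"),
                   row.names = FALSE, quote = FALSE)
  invisible(out_prefix)
}

#' Read a GMT gene-set file
#'
#' @param path GMT file (tab-separated: set name, description, genes...).
#' @return named list of character vectors.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  sets <- lapply(lines, function(l) {
    parts <- strsplit(l, "\t", fixed = TRUE)[[1]]
    parts[-(1:2)]
  })
  names(sets) <- vapply(lines, function(l) strsplit(l, "\t", fixed = TRUE)[[1]][1], "")
  sets
}

#' Run the tracing analysis pipeline end to end
#'
#' Generates (or loads) a tracing cohort, computes the fragment-level
#' labelling metrics, and runs the nested fragment-within-patient
#' comparison for each metric between the two tissue classes. Optionally
#' runs the QC pipeline on a feature table and an OxPhos/survival analysis
#' on an expression cohort. All randomness flows from `seed`.
#'
#' @param config list with optional entries: `cohort` (a `cohort_spec` or a
#'   path to a MID CSV), `seed`, `qc` (`TRUE` or a `feature_table`),
#'   `survival` (`TRUE` or a list as from [generate_survival_cohort()]),
#'   `out` (path for the JSON report).
#' @return the report list (invisibly written as JSON when `out` is set).
#' @export
run_pipeline <- function(config = list()) {
  seed <- config$seed %||% 1L
  report <- list(seed = seed)

  cohort <- config$cohort %||% cohort_spec()
  if (is.character(cohort)) {
    cohort <- read_mid_table(cohort)
  } else if (inherits(cohort, "cohort_spec")) {
    cohort <- generate_tracing_cohort(cohort, seed = seed)
  }
  if (is.null(cohort$mids) || nrow(cohort$mids) == 0)
    stop("run_pipeline: empty cohort")
  metrics <- fragment_metrics(cohort)
  report$n_fragments <- length(unique(metrics$fragment))
  report$n_patients <- length(unique(metrics$patient))

  tests <- list()
  if (length(unique(metrics$tissue)) == 2) {
    for (m in unique(metrics$metric)) {
      sub <- metrics[metrics$metric == m & is.finite(metrics$value), ]
      if (length(unique(sub$tissue)) != 2) next
      nc <- tryCatch(nested_comparison(sub$value, sub$patient, sub$tissue),
                     error = function(e) NULL)
      if (is.null(nc)) next
      tests[[m]] <- list(p = nc$p, statistic = nc$statistic,
                         class_means = as.list(nc$class_means))
    }
    ps <- vapply(tests, function(t) t$p, numeric(1))
    adj <- bh_adjust(ps)
    for (i in seq_along(tests)) tests[[i]]$p_adj <- unname(adj[i])
  }
  report$metrics <- metrics
  report$nested_tests <- tests

  if (isTRUE(config$qc) || inherits(config$qc, "feature_table")) {
    ft <- if (inherits(config$qc, "feature_table")) config$qc else
      generate_feature_table(seed = seed)
    qc <- run_qc_pipeline(ft)
    report$qc <- list(n_features_out = nrow(qc$table$intensities),
                      snr_dropped = qc$report$snr_dropped,
                      loess_corrected = qc$report$loess$loess_corrected)
  }

  if (isTRUE(config$survival) || is.list(config$survival)) {
    sc <- if (is.list(config$survival) && !isTRUE(config$survival))
      config$survival else generate_survival_cohort(seed = seed)
    score <- oxphos_score(sc$expr, sc$gene_set, log_scale = TRUE)
    strat <- stratify(score, "median")
    lr <- logrank_test(sc$clinical$time_days, sc$clinical$event, strat)
    med <- vapply(c("high", "low"), function(g) {
      k <- km_estimate(sc$clinical$time_days[strat == g],
                       sc$clinical$event[strat == g])
      if (is.na(k$median)) -1 else k$median
    }, numeric(1))
    report$survival <- list(logrank_p = lr$p, statistic = lr$statistic,
                            median_high = med[["high"]], median_low = med[["low"]])
  }

  if (!is.null(config$out)) {
    jsonlite::write_json(report, config$out, auto_unbox = TRUE, digits = NA,
                         dataframe = "rows")
  }
  report
}
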