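#' OxPhos gene-set score
#'
#' Per-sample summary of oxidative-phosphorylation gene-set expression:
#' expression is restricted to the set genes present in the matrix,
#' log2-transformed if on a linear scale, mean-centred and z-scaled per
#' gene, and the first principal component of the samples is extracted as
#' the score. The sign of PC1 is fixed so the score correlates positively
#' with mean set expression ("high OxPhos" = high expression).
#'
#' @param expr numeric matrix, genes x samples (rownames = gene ids).
#' @param gene_set character vector of gene ids; ids absent from the matrix
#'   are ignored.
#' @param log_scale `TRUE` if `expr` is already on a log scale.
#' @return named numeric vector of scores (one per sample) with attributes
#'   `"var_explained"` (fraction of variance on PC1), `"n_genes"` and
#'   `"dropped"` (zero-variance genes removed).
#' @export
oxphos_score <- function(expr, gene_set, log_scale = FALSE) {
  expr <- as.matrix(expr)
  if (is.null(rownames(expr))) stop("oxphos_score: expression matrix needs gene rownames")
  if (ncol(expr) < 2) stop("oxphos_score: need at least 2 samples")
  genes <- intersect(unique(gene_set), rownames(expr))
  if (length(genes) < 2) stop("oxphos_score: fewer than 2 set genes in the matrix")
  X <- expr[genes, , drop = FALSE]
  if (!log_scale) X <- log2(X + 1)
  sds <- apply(X, 1, stats::sd)
  dropped <- rownames(X)[sds == 0]
  X <- X[sds > 0, , drop = FALSE]
  if (nrow(X) < 2) stop("oxphos_score: fewer than 2 set genes with nonzero variance")
  Z <- t(scale(t(X)))  # per-gene centre and z-scale
  pc <- stats::prcomp(t(Z), center = FALSE, scale. = FALSE)
  score <- pc$x[, 1]
  if (stats::cor(score, colMeans(Z)) < 0) score <- -score
  attr(score, "var_explained") <- pc$sdev[1]^2 / sum(pc$sdev^2)
  attr(score, "n_genes") <- nrow(X)
  attr(score, "dropped") <- dropped
  score
}

#' Stratify a cohort by score
#'
#' Labels samples `"high"`/`"low"` by either a median split (values at or
#' below the cut go to `"low"`; deterministic tie policy) or a 30/70
#' quantile rule leaving the middle 40% unlabelled (`NA`). An optional
#' grade/stage filter restricts the subcohort first; samples outside the
#' filter get `NA`.
#'
#' @param values numeric scores.
#' @param rule `"median"` or `"quantile"` (30/70).
#' @param grade,stage optional per-sample vectors used with `grade_set` /
#'   `stage_set` filters.
#' @param grade_set,stage_set values to keep (e.g. `c(3, 4)`).
#' @return character vector of `"high"`, `"low"` or `NA`.
#' @export
stratify <- function(values, rule = c("median", "quantile"),
                     grade = NULL, stage = NULL,
                     grade_set = NULL, stage_set = NULL) {
  rule <- match.arg(rule)
  keep <- rep(TRUE, length(values))
  if (!is.null(grade_set)) keep <- keep & grade %in% grade_set
  if (!is.null(stage_set)) keep <- keep & stage %in% stage_set
  if (!any(keep)) stop("stratify: the grade/stage filter leaves no samples")
  v <- values[keep]
  if (length(unique(v)) < 2) stop("stratify: all values identical, no informative split")
  lab <- rep(NA_character_, length(values))
  if (rule == "median") {
    cut <- stats::median(v)
    lab[keep] <- ifelse(v > cut, "high", "low")
  } else {
    q <- stats::quantile(v, c(0.3, 0.7), names = FALSE)
    lab[keep][v <= q[1]] <- "low"
    lab[keep][v >= q[2]] <- "high"
  }
  lab
}

#' Kaplan-Meier estimate
#'
#' Product-limit survival curve and median survival (first time the curve
#' drops to 0.5 or below; `NA` = not reached).
#'
#' @param time survival times (nonnegative).
#' @param event event indicator (1 = death/event, 0 = censored).
#' @return list with `time`, `surv` (step-function values after each
#'   distinct event time), `median`, and the underlying
#'   [survival::survfit] object as `fit`.
#' @export
km_estimate <- function(time, event) {
  if (any(time < 0)) stop("km_estimate: negative survival times")
  if (sum(event) < 1) {
    fit <- survival::survfit(survival::Surv(time, event) ~ 1)
    return(list(time = fit$time, surv = fit$surv, median = NA_real_, fit = fit))
  }
  fit <- survival::survfit(survival::Surv(time, event) ~ 1)
  med <- unname(summary(fit)$table["median"])
  list(time = fit$time, surv = fit$surv, median = med, fit = fit)
}

#' Log-rank (Mantel-Cox) test
#'
#' Standard observed-minus-expected chi-square with hypergeometric variance
#' on one degree of freedom.
#'
#' @param time,event survival data.
#' @param group two-level group labels.
#' @return list with `statistic`, `p`, and per-group observed/expected
#'   event counts.
#' @export
logrank_test <- function(time, event, group) {
  group <- as.factor(group)
  if (nlevels(droplevels(group)) != 2)
    stop("logrank_test: exactly two non-empty groups required")
  if (sum(event) < 1) stop("logrank_test: no events")
  sd_ <- survival::survdiff(survival::Surv(time, event) ~ group)
  stat <- unname(sd_$chisq)
  list(statistic = stat, p = stats::pchisq(stat, df = 1, lower.tail = FALSE),
       observed = sd_$obs, expected = sd_$exp)
}

#' Nested fragment-within-patient comparison
#'
#' Two tissue classes measured on multiple fragments per patient are
#' compared with patient as the experimental unit: a two-level nested ANOVA
#' with patients nested in tissue class, testing the class effect against
#' the between-patient variation (two-sided). In the balanced case this is
#' algebraically the pooled-variance t-test on patient means. Also returns
#' the per-patient mean and SD used for plotting.
#'
#' @param value fragment-level metric values.
#' @param patient patient identifiers.
#' @param tissue tissue class per fragment (two levels). A patient
#'   contributing fragments to both classes is treated as two independent
#'   units (no pairing assumed).
#' @return list with `p`, `statistic` (F on 1 and `n_patients - 2` df),
#'   `patient_summary` (patient, tissue, mean, sd, n_fragments) and
#'   `class_means`.
#' @export
nested_comparison <- function(value, patient, tissue) {
  ok <- is.finite(value)
  value <- value[ok]; patient <- patient[ok]; tissue <- tissue[ok]
  tissue <- droplevels(as.factor(tissue))
  if (nlevels(tissue) != 2) stop("nested_comparison: exactly two tissue classes required")
  unit <- interaction(tissue, patient, drop = TRUE)
  per_pat <- data.frame(
    patient = tapply(as.character(patient), unit, function(x) x[1]),
    tissue = tapply(as.character(tissue), unit, function(x) x[1]),
    mean = as.numeric(tapply(value, unit, mean)),
    sd = as.numeric(tapply(value, unit, stats::sd)),
    n_fragments = as.integer(tapply(value, unit, length)),
    stringsAsFactors = FALSE)
  rownames(per_pat) <- NULL
  n_units <- table(per_pat$tissue)
  if (any(n_units < 2)) stop("nested_comparison: need >= 2 patients per class")

  # nested ANOVA: class tested against patients-within-class
  grand <- mean(per_pat$mean)  # equal patient weights
  cls_means <- tapply(per_pat$mean, per_pat$tissue, mean)
  ss_class <- sum(n_units * (cls_means - grand)^2)
  ss_patient <- sum((per_pat$mean - cls_means[per_pat$tissue])^2)
  df_class <- 1L
  df_patient <- nrow(per_pat) - 2L
  Fstat <- (ss_class / df_class) / (ss_patient / df_patient)
  p <- stats::pf(Fstat, df_class, df_patient, lower.tail = FALSE)
  list(p = p, statistic = Fstat, df = c(df_class, df_patient),
       patient_summary = per_pat,
       class_means = cls_means)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up adjusted p values (wrapper over [stats::p.adjust]).
#'
#' @param p numeric vector of p values in `[0, 1]`.
#' @export
bh_adjust <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("bh_adjust: p values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' One-way ANOVA with Tukey or Dunnett multiple-comparison adjustment
#'
#' Thin standard procedure over grouped values, used for multi-subtype
#' comparisons (Tukey all-pairs) or comparisons against a reference tissue
#' (Dunnett).
#'
#' @param value numeric response.
#' @param group group labels; for Dunnett the first factor level is the
#'   reference.
#' @param adjust `"tukey"` or `"dunnett"`.
#' @return data frame of contrasts with estimates and adjusted p values,
#'   with the overall ANOVA p in the `"anova_p"` attribute.
#' @export
group_anova <- function(value, group, adjust = c("tukey", "dunnett")) {
  adjust <- match.arg(adjust)
  d <- data.frame(value = value, group = droplevels(as.factor(group)))
  fit <- stats::aov(value ~ group, data = d)
  anova_p <- summary(fit)[[1]][["Pr(>F)"]][1]
  if (adjust == "tukey") {
    tk <- stats::TukeyHSD(fit)$group
    out <- data.frame(contrast = rownames(tk), estimate = tk[, "diff"],
                      p_adj = tk[, "p adj"], row.names = NULL)
  } else {
    gl <- multcomp::glht(fit, linfct = multcomp::mcp(group = "Dunnett"))
    sm <- summary(gl)
    out <- data.frame(contrast = names(sm$test$coefficients),
                      estimate = as.numeric(sm$test$coefficients),
                      p_adj = as.numeric(sm$test$pvalues), row.names = NULL)
  }
  attr(out, "anova_p") <- anova_p
  out
}
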