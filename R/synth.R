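#' Default tissue-class TCA parameter priors
#'
#' Central parameter sets for the two default tissue classes of the
#' synthetic tracing cohort. The adjacent kidney runs a fast, oxidative
#' cycle (high turnover, high PDH contribution, little reductive
#' carboxylation); the clear-cell tumour class has suppressed turnover and
#' PDH contribution and an enhanced reductive fraction.
#'
#' @name class_params
#' @export
kidney_params <- function() {
  tca_params(turnover = 0.90, pdh_fraction = 0.75, reductive_fraction = 0.05)
}

#' @rdname class_params
#' @export
tumour_params <- function() {
  tca_params(turnover = 0.45, pdh_fraction = 0.35, reductive_fraction = 0.30)
}

#' Specification of a synthetic tracing cohort
#'
#' @param classes named list of `tca_params`, one per tissue class.
#' @param patients_per_class number of patients drawn from each class.
#' @param fragments_per_patient tissue fragments measured per patient.
#' @param kappa Dirichlet concentration of the fragment-level compositional
#'   measurement noise on each MID (500 gives roughly 2% SD on major
#'   fractions).
#' @param param_sd SD of the patient-level log-normal perturbation applied
#'   to each fractional parameter (clamped back to `[0, 1]`).
#' @param tracer a `tracer_spec` shared by the cohort.
#' @return list of class `cohort_spec`.
#' @export
cohort_spec <- function(classes = list(adjacent_kidney = kidney_params(),
                                       ccRCC = tumour_params()),
                        patients_per_class = 10L,
                        fragments_per_patient = 3L,
                        kappa = 500,
                        param_sd = 0.25,
                        tracer = tracer_spec("glucose")) {
  stopifnot(kappa > 0, patients_per_class >= 1L, fragments_per_patient >= 1L,
            param_sd >= 0, length(classes) >= 1, !is.null(names(classes)))
  structure(list(classes = classes, patients_per_class = as.integer(patients_per_class),
                 fragments_per_patient = as.integer(fragments_per_patient),
                 kappa = kappa, param_sd = param_sd, tracer = tracer),
            class = "cohort_spec")
}

perturb_params <- function(params, sd) {
  if (sd == 0) return(params)
  frac_fields <- c("acetyl_enrichment", "pdh_fraction", "pc_fraction",
                   "anaplerosis_unlabelled", "turnover", "reductive_fraction",
                   "glu_exchange", "dilution")
  p <- unclass(params)
  for (f in frac_fields) p[[f]] <- min(1, max(0, p[[f]] * stats::rlnorm(1, 0, sd)))
  if (p$pc_fraction + p$anaplerosis_unlabelled > 1) {
    s <- p$pc_fraction + p$anaplerosis_unlabelled
    p$pc_fraction <- p$pc_fraction / s
    p$anaplerosis_unlabelled <- p$anaplerosis_unlabelled / s
  }
  do.call(tca_params, p)
}

rdirichlet_noise <- function(mid, kappa) {
  shape <- mid * kappa
  g <- vapply(shape, function(a) if (a <= 0) 0 else stats::rgamma(1, shape = a), numeric(1))
  if (sum(g) <= 0) return(mid)
  g / sum(g)
}

#' Generate a synthetic tracing cohort
#'
#' Draws patient-level TCA parameters from each tissue class prior, runs the
#' deterministic simulator per patient, and adds Dirichlet compositional
#' noise to each fragment's MIDs. Plasma MIDs (glucose m+6, pyruvate m+3 at
#' the tracer enrichment) are attached per patient. Deterministic given
#' `seed`.
#'
#' @param spec a `cohort_spec`.
#' @param seed integer seed.
#' @return list with `mids` (long data frame: patient, fragment, tissue,
#'   metabolite, isotopologue, fraction), `plasma` (patient, metabolite,
#'   isotopologue, fraction), `glu45` (per-fragment [4,5-13C]glutamate
#'   fraction) and `patient_params`.
#' @export
generate_tracing_cohort <- function(spec = cohort_spec(), seed = 1L) {
  stopifnot(inherits(spec, "cohort_spec"))
  set.seed(seed)
  mid_rows <- list(); glu_rows <- list(); plasma_rows <- list()
  patient_params <- list()
  pat_i <- 0L
  for (cls in names(spec$classes)) {
    for (p in seq_len(spec$patients_per_class)) {
      pat_i <- pat_i + 1L
      pid <- sprintf("P%03d", pat_i)
      params <- perturb_params(spec$classes[[cls]], spec$param_sd)
      patient_params[[pid]] <- params
      sim <- simulate_tca(spec$tracer, params)
      e <- spec$tracer$enrichment
      plasma_rows[[pid]] <- data.frame(
        patient = pid,
        metabolite = c(rep("glucose", 7), rep("pyruvate", 4)),
        isotopologue = c(0:6, 0:3),
        fraction = c(c(1 - e, 0, 0, 0, 0, 0, e), c(1 - e, 0, 0, e)),
        stringsAsFactors = FALSE)
      for (f in seq_len(spec$fragments_per_patient)) {
        fid <- sprintf("%s_f%d", pid, f)
        for (met in c("pyruvate", "citrate", "succinate", "fumarate",
                      "malate", "glutamate")) {
          noisy <- rdirichlet_noise(sim$mids[[met]], spec$kappa)
          mid_rows[[length(mid_rows) + 1L]] <- data.frame(
            patient = pid, fragment = fid, tissue = cls, metabolite = met,
            isotopologue = seq_along(noisy) - 1L, fraction = noisy,
            stringsAsFactors = FALSE)
        }
        g45 <- as.numeric(glu45_fraction(sim$states$glutamate))
        glu_rows[[length(glu_rows) + 1L]] <- data.frame(
          patient = pid, fragment = fid, tissue = cls, value = g45,
          stringsAsFactors = FALSE)
      }
    }
  }
  list(mids = do.call(rbind, mid_rows),
       plasma = do.call(rbind, plasma_rows),
       glu45 = do.call(rbind, glu_rows),
       patient_params = patient_params)
}

#' Generate a synthetic LC/GC-MS feature table
#'
#' Log-normal study intensities with QC samples injected at fixed intervals
#' (pooled profile plus multiplicative noise at `qc_cv`), blanks at a fixed
#' fraction of the mean signal, and optional multiplicative run-order drift
#' (linear factor 1 at the first injection to `drift_factor` at the last)
#' applied to a chosen subset of features on all non-blank samples.
#'
#' @param n_features,n_study numbers of features and study samples.
#' @param n_qc,n_blank numbers of QC and blank injections.
#' @param drift_factor terminal drift multiplier (1 = no drift).
#' @param n_drifted how many features drift (the first `n_drifted`).
#' @param qc_cv coefficient of variation of QC replicate noise.
#' @param blank_fraction blank signal as a fraction of the mean profile.
#' @param seed integer seed.
#' @return a `feature_table`; drifted features are named in the
#'   `"drifted"` attribute.
#' @export
generate_feature_table <- function(n_features = 40L, n_study = 116L,
                                   n_qc = 30L, n_blank = 4L,
                                   drift_factor = 1, n_drifted = 0L,
                                   qc_cv = 0.05, blank_fraction = 0.01,
                                   seed = 1L) {
  set.seed(seed)
  n_total <- n_study + n_qc + n_blank
  base <- stats::rlnorm(n_features, meanlog = log(1e6), sdlog = 1)
  types <- rep("study", n_total)
  # QCs at fixed intervals through the run, blanks at the start
  blank_pos <- seq_len(n_blank)
  qc_pos <- round(seq(n_blank + 1, n_total, length.out = n_qc))
  types[blank_pos] <- "blank"
  types[qc_pos] <- "QC"
  M <- matrix(0, n_features, n_total)
  for (j in seq_len(n_total)) {
    if (types[j] == "blank") {
      M[, j] <- base * blank_fraction * stats::rlnorm(n_features, 0, 0.3)
    } else if (types[j] == "QC") {
      M[, j] <- base * stats::rlnorm(n_features, 0, sqrt(log(1 + qc_cv^2)))
    } else {
      M[, j] <- base * stats::rlnorm(n_features, 0, 0.4)
    }
  }
  if (drift_factor != 1 && n_drifted > 0) {
    drift <- 1 + (drift_factor - 1) * (seq_len(n_total) - 1) / (n_total - 1)
    idx <- seq_len(min(n_drifted, n_features))
    for (j in which(types != "blank")) M[idx, j] <- M[idx, j] * drift[j]
  }
  samples <- data.frame(sample = sprintf("S%03d", seq_len(n_total)),
                        run_order = seq_len(n_total), type = types,
                        batch = 1L, stringsAsFactors = FALSE)
  modes <- rep(c("positive", "negative"), length.out = n_features)
  features <- data.frame(feature = sprintf("M%03d", seq_len(n_features)),
                         mode = modes,
                         hmdb = sprintf("HMDB%07d", seq_len(n_features)),
                         stringsAsFactors = FALSE)
  ft <- feature_table(M, samples, features)
  attr(ft, "drifted") <- features$feature[seq_len(min(n_drifted, n_features))]
  ft
}

#' Generate a synthetic expression/survival cohort
#'
#' Each sample carries a latent standard-normal OxPhos activity `z`; the
#' gene-set genes are shifted by `z * set_effect` (in SD units) on the log2
#' scale, other genes are pure noise. Survival is exponential with hazard
#' `base_hazard * exp(beta * z)`; censoring is independent exponential
#' calibrated to the requested rate. Grades and stages are assigned with
#' higher-`z` samples enriched for high grade/stage.
#'
#' @param n number of samples (>= 10).
#' @param n_genes total genes; the first `n_set` form the gene set.
#' @param n_set gene-set size.
#' @param set_effect shift per latent SD on set genes.
#' @param beta log-hazard per latent SD (0 = null).
#' @param censor_rate target fraction censored (1 = everything censored).
#' @param base_hazard baseline exponential hazard per day.
#' @param seed integer seed.
#' @return list with `expr` (log2-scale genes x samples matrix),
#'   `gene_set`, and `clinical` (sample, time_days, event, grade, stage,
#'   latent score `z`).
#' @export
generate_survival_cohort <- function(n = 200L, n_genes = 300L, n_set = 50L,
                                     set_effect = 1, beta = 1,
                                     censor_rate = 0.3, base_hazard = 1 / 1500,
                                     seed = 1L) {
  stopifnot(n >= 10L, n_set >= 2L, n_genes >= n_set)
  set.seed(seed)
  z <- stats::rnorm(n)
  expr <- matrix(stats::rnorm(n_genes * n), n_genes, n)
  expr[seq_len(n_set), ] <- expr[seq_len(n_set), ] +
    matrix(rep(z * set_effect, each = n_set), n_set, n)
  expr <- expr + 6  # plausible log2 expression level
  rownames(expr) <- sprintf("G%04d", seq_len(n_genes))
  colnames(expr) <- sprintf("S%04d", seq_len(n))
  gene_set <- rownames(expr)[seq_len(n_set)]

  t_event <- stats::rexp(n, rate = base_hazard * exp(beta * z))
  if (censor_rate >= 1) {
    time <- t_event * stats::runif(n, 0.2, 0.8)
    event <- rep(0L, n)
  } else if (censor_rate <= 0) {
    time <- t_event; event <- rep(1L, n)
  } else {
    c_rate <- base_hazard * censor_rate / max(1e-12, 1 - censor_rate)
    t_cens <- stats::rexp(n, rate = c_rate)
    event <- as.integer(t_event <= t_cens)
    time <- pmin(t_event, t_cens)
  }
  grade <- ifelse(stats::pnorm(z) + stats::runif(n, -0.25, 0.25) > 0.5,
                  sample(3:4, n, TRUE), sample(1:2, n, TRUE))
  stage <- ifelse(stats::pnorm(z) + stats::runif(n, -0.25, 0.25) > 0.5,
                  sample(3:4, n, TRUE), sample(1:2, n, TRUE))
  clinical <- data.frame(sample = colnames(expr), time_days = time,
                         event = event, grade = grade, stage = stage, z = z,
                         stringsAsFactors = FALSE)
  list(expr = expr, gene_set = gene_set, clinical = clinical)
}
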