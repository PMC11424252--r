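make_toy_table <- function() {
  # 3 features x 8 samples: 2 blanks, 3 QCs, 3 study
  M <- rbind(M1 = c(10, 10, 100, 110, 100, 90, 95, 105),
             M2 = c(10, 10, 10, 12, 10, 11, 9, 10),
             M3 = c(0, 0, 50, 50, 50, 48, 52, 50))
  samples <- data.frame(sample = paste0("S", 1:8), run_order = 1:8,
                        type = c("blank", "blank", "QC", "QC", "QC",
                                 "study", "study", "study"))
  feature_table(M, samples,
                data.frame(feature = c("M1", "M2", "M3"),
                           mode = c("positive", "negative", "positive"),
                           hmdb = c("H1", "H2", "H3")))
}

test_that("signal-to-noise is QC median over blank median", {
  s <- snr(make_toy_table())
  expect_equal(s$snr[1], 100 / 10)
  expect_equal(s$snr[2], 10 / 10)
  expect_true(is.infinite(s$snr[3]) && s$infinite[3])
  ft <- make_toy_table(); ft$samples$type[ft$samples$type == "blank"] <- "study"
  expect_error(snr(ft), "blank")
})

test_that("the run-order test flags monotone QC trends and BH-adjusts", {
  set.seed(8)
  ft <- generate_feature_table(n_features = 10, drift_factor = 2, n_drifted = 3,
                               seed = 8)
  tr <- run_order_test(ft)
  drifted <- attr(ft, "drifted")
  expect_true(all(tr$p_adj[tr$feature %in% drifted] <= 0.05))
  expect_true(all(tr$rho[tr$feature %in% drifted] > 0.5))

  # constant QC intensities give a missing correlation, not an error
  M <- matrix(5, 2, 10)
  samples <- data.frame(sample = paste0("S", 1:10), run_order = 1:10,
                        type = c("blank", rep(c("QC", "study"), length.out = 9)))
  tr2 <- run_order_test(feature_table(M, samples))
  expect_true(all(is.na(tr2$p)))
})

test_that("LOESS correction is applied only where the QC trend is significant", {
  ft <- generate_feature_table(drift_factor = 2, n_drifted = 8, seed = 21)
  tr <- run_order_test(ft)
  out <- loess_drift_correct(ft, tr)
  lg <- attr(out, "qc_log")
  flagged <- tr$feature[!is.na(tr$p_adj) & tr$p_adj <= 0.05]
  expect_setequal(c(lg$loess_corrected, lg$loess_skipped), flagged)
  untouched <- setdiff(rownames(ft$intensities), c(lg$loess_corrected, lg$loess_skipped))
  expect_equal(ft$intensities[untouched, ], out$intensities[untouched, ])

  # corrected drifted features: QC coefficient of variation at least halved
  qcidx <- ft$samples$type == "QC"
  drifted <- intersect(attr(ft, "drifted"), lg$loess_corrected)
  expect_gt(length(drifted), 0)
  cv <- function(x) sd(x) / mean(x)
  for (f in drifted)
    expect_lt(cv(out$intensities[f, qcidx]), 0.5 * cv(ft$intensities[f, qcidx]))
})

test_that("TIC normalization equalizes proportional sample loading", {
  base <- c(100, 200, 50, 400, 800, 120, 60, 90)
  loading <- c(0.01, 1.02, 0.98, 1.01, 0.99, 1, 2, 0.5, 1.5, 1.2)
  M <- outer(base, loading)
  samples <- data.frame(sample = paste0("S", 1:10), run_order = 1:10,
                        type = c("blank", rep("QC", 4), rep("study", 5)))
  ft <- feature_table(M, samples)
  norm <- tic_normalize(ft, qc_config(stable_snr_min = 1))
  # every sample becomes the same profile
  expect_lt(max(apply(norm$table$intensities, 1, function(x) diff(range(x)))), 1e-9)
  # factors recompute by hand: per-sample stable-median over grand median
  med <- apply(M, 2, median)
  expect_equal(unname(norm$factors), med / median(med))
  # idempotence: normalizing twice equals once
  norm2 <- tic_normalize(norm$table, qc_config(stable_snr_min = 1))
  expect_equal(norm2$table$intensities, norm$table$intensities, tolerance = 1e-12)
  expect_error(tic_normalize(ft, qc_config(stable_cv_max = 1e-9, stable_snr_min = 1e6)),
               "no stable features")
})

test_that("log transform imputes zeros and mode dedup keeps the higher-S/N row", {
  M <- rbind(A_pos = c(5, 5, 100, 100, 100, 80, 120),
             A_neg = c(1, 1, 100, 100, 100, 80, 120),
             B_pos = c(2, 2, 0, 40, 40, 40, 40))
  samples <- data.frame(sample = paste0("S", 1:7), run_order = 1:7,
                        type = c("blank", "blank", "QC", "QC", "QC", "study", "study"))
  feats <- data.frame(feature = c("A_pos", "A_neg", "B_pos"),
                      mode = c("positive", "negative", "positive"),
                      hmdb = c("HA", "HA", "HB"))
  ft <- feature_table(M, samples, feats)
  out <- log_transform_and_dedupe(ft)
  # A_neg has S/N 100 vs 20 for A_pos: the negative-mode row is retained
  expect_setequal(rownames(out$intensities), c("A_neg", "B_pos"))
  # zero imputed with half the minimum positive, then log10
  expect_equal(out$intensities["B_pos", 3], log10(1))
  expect_equal(attr(out, "qc_log")$zero_imputed, "B_pos")
  expect_equal(nrow(out$intensities), length(unique(feats$hmdb)))
})

test_that("Cohen's d and cross-study concordance behave as designed", {
  set.seed(99)
  expect_true(is.na(cohen_d(rep(1, 5), rep(1, 5))))
  d <- cohen_d(rnorm(10000, 1), rnorm(10000, 0))
  expect_equal(d, 1, tolerance = 0.05)
  x <- rnorm(20, 5); expect_equal(cohen_d(x, x), 0)

  M <- matrix(rlnorm(30 * 12, log(1e5), 1), 30, 12)
  M[1:10, 7:12] <- M[1:10, 7:12] * 4
  hmdb <- sprintf("H%02d", 1:30)
  es <- effect_sizes_and_crossstudy(M, rep(c(FALSE, TRUE), each = 6), hmdb)
  self <- effect_sizes_and_crossstudy(M, rep(c(FALSE, TRUE), each = 6), hmdb,
                                      external = data.frame(hmdb = hmdb,
                                                            d = es$effects$d))
  expect_equal(self$correlation, 1)
  expect_equal(self$n_matched, 30)
  expect_true(mean(es$effects$d[1:10]) > mean(es$effects$d[11:30]))
})

test_that("the full pipeline keeps undrifted, equal-loading tables at a log map", {
  ft <- generate_feature_table(n_features = 20, drift_factor = 1, seed = 13)
  res <- run_qc_pipeline(ft, qc_config(snr_min = 3))
  kept <- rownames(res$table$intensities)
  not_loessed <- setdiff(kept, res$report$loess$loess_corrected)
  # for features without LOESS correction, output = log10(input / factor)
  f <- res$report$tic_factors
  for (feat in not_loessed[1:5]) {
    raw <- ft$intensities[feat, ]
    expect_equal(res$table$intensities[feat, ], log10(raw / f), tolerance = 1e-12)
  }
})
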