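test_that("the gene-set score is PC1 oriented towards high set expression", {
  # rank-1 case: two perfectly correlated set genes
  prof <- c(1, 3, 2, 5, 4)
  expr <- rbind(g1 = prof, g2 = 2 * prof + 1, g3 = c(9, 1, 4, 2, 7))
  colnames(expr) <- paste0("s", 1:5)
  sc <- oxphos_score(expr, c("g1", "g2"), log_scale = TRUE)
  expect_equal(attr(sc, "var_explained"), 1)
  expect_equal(cor(sc, prof), 1, tolerance = 1e-12)

  # invariance to gene order and to set genes absent from the matrix
  sc2 <- oxphos_score(expr, c("g_absent", "g2", "g1"), log_scale = TRUE)
  expect_equal(unname(sc), unname(sc2))

  # permutation equivariance
  perm <- c(3, 1, 5, 2, 4)
  sc3 <- oxphos_score(expr[, perm], c("g1", "g2"), log_scale = TRUE)
  expect_equal(as.numeric(sc3), as.numeric(sc[perm]))

  # shifted cohorts score higher
  hits <- 0
  for (s in 1:25) {
    coh <- generate_survival_cohort(n = 60, set_effect = 1, beta = 0, seed = s)
    grp_b <- coh$clinical$z > median(coh$clinical$z)
    scr <- oxphos_score(coh$expr, coh$gene_set, log_scale = TRUE)
    if (median(scr[grp_b]) > median(scr[!grp_b])) hits <- hits + 1
  }
  expect_equal(hits, 25)
  expect_error(oxphos_score(expr, "g1", log_scale = TRUE), "fewer than 2")
})

test_that("stratification implements the median and 30/70 quantile rules", {
  v <- 1:10
  med <- stratify(v, "median")
  expect_equal(med, rep(c("low", "high"), each = 5))
  q <- stratify(v, "quantile")
  expect_equal(q, c("low", "low", "low", NA, NA, NA, NA, "high", "high", "high"))

  # ties at the median cut go to "low"
  expect_equal(stratify(c(1, 2, 2, 3), "median"), c("low", "low", "low", "high"))

  # grade/stage filtered subcohort
  g <- c(1, 3, 4, 3, 2, 4); st <- c(3, 3, 4, 1, 4, 3)
  lab <- stratify(1:6, "median", grade = g, stage = st,
                  grade_set = c(3, 4), stage_set = c(3, 4))
  expect_true(all(is.na(lab[c(1, 4, 5)])))
  expect_equal(lab[c(2, 3, 6)], c("low", "low", "high"))
  expect_error(stratify(rep(1, 5), "median"), "identical")
})

test_that("Kaplan-Meier estimates match the hand product-limit table", {
  time <- c(1, 2, 3, 4, 4, 5); event <- c(1, 0, 1, 1, 0, 0)
  km <- km_estimate(time, event)
  hand <- oracle_km(time, event)
  idx <- match(hand$time, km$time)
  expect_equal(km$surv[idx], hand$surv, tolerance = 1e-12)
  expect_equal(hand$surv, c(5 / 6, 5 / 8, 5 / 12))
  expect_equal(km$median, 4)

  # single subject with an event at t = 5
  km1 <- km_estimate(5, 1)
  expect_equal(km1$surv, 0)
  expect_equal(km1$median, 5)

  # all censored: curve stays at 1, median not reached
  km0 <- km_estimate(c(3, 6, 9), c(0, 0, 0))
  expect_true(all(km0$surv == 1))
  expect_true(is.na(km0$median))
  expect_error(km_estimate(c(-1, 2), c(1, 1)), "negative")
})

test_that("the log-rank test matches its definition and the permutation oracle", {
  # identical groups: statistic 0, p = 1
  time <- c(2, 4, 6, 8, 2, 4, 6, 8); event <- rep(1, 8)
  lr <- logrank_test(time, event, rep(c("A", "B"), each = 4))
  expect_equal(lr$statistic, 0, tolerance = 1e-12)
  expect_equal(lr$p, 1)

  # statistic equals the hand observed-minus-expected form, label-symmetric
  set.seed(31)
  t2 <- rexp(16, 1 / 10); e2 <- rbinom(16, 1, 0.8)
  g2 <- rep(c("A", "B"), each = 8)
  lr2 <- logrank_test(t2, e2, g2)
  expect_equal(lr2$statistic, oracle_logrank_stat(t2, e2, g2), tolerance = 1e-9)
  lr2b <- logrank_test(t2, e2, ifelse(g2 == "A", "B", "A"))
  expect_equal(lr2b$statistic, lr2$statistic)

  # 5+5 toy set against the exhaustive 252-assignment permutation p
  t5 <- c(2, 4, 6, 8, 10, 3, 7, 12, 14, 16)
  e5 <- c(1, 1, 1, 1, 1, 1, 1, 1, 0, 1)
  lr5 <- logrank_test(t5, e5, rep(c("A", "B"), each = 5))
  p_perm <- oracle_logrank_perm_p(t5, e5)
  expect_lt(abs(lr5$p - p_perm), 0.05)

  # strong separation: all A events precede all B events
  lr6 <- logrank_test(c(1:5, 11:15), rep(1, 10), rep(c("A", "B"), each = 5))
  expect_lt(lr6$p, 0.01)
  expect_error(logrank_test(c(1, 2), c(1, 1), c("A", "A")), "two")
})

test_that("the nested comparison tests classes against patient variation", {
  # identical per-patient means -> p near 1
  pat <- rep(sprintf("p%d", 1:6), each = 3)
  cls <- rep(c("kidney", "tumour"), each = 9)
  val <- rep(c(1, 2, 3, 1, 2, 3), each = 3) + rep(c(-0.1, 0, 0.1), 6)
  nc <- nested_comparison(val, pat, cls)
  expect_gt(nc$p, 0.9)
  expect_equal(nrow(nc$patient_summary), 6)
  expect_equal(nc$patient_summary$n_fragments, rep(3L, 6))

  # balanced case: equal to the pooled-variance t-test on patient means
  set.seed(7)
  val2 <- rnorm(18, mean = rep(c(0, 1), each = 9))
  nc2 <- nested_comparison(val2, pat, cls)
  means <- tapply(val2, pat, mean)
  tt <- t.test(means[1:3], means[4:6], var.equal = TRUE)
  expect_equal(nc2$p, tt$p.value, tolerance = 1e-12)
  expect_equal(nc2$statistic, unname(tt$statistic)^2, tolerance = 1e-12)

  # power under the stated hierarchical design
  rej <- 0
  for (s in 1:40) {
    set.seed(s)
    pm <- c(rnorm(10, 0, 0.3), rnorm(10, 1, 0.3))
    v <- rep(pm, each = 3) + rnorm(60, 0, 0.2)
    p <- rep(sprintf("q%02d", 1:20), each = 3)
    cl <- rep(c("A", "B"), each = 30)
    if (nested_comparison(v, p, cl)$p <= 0.05) rej <- rej + 1
  }
  expect_gte(rej, 36)  # >= 90%
  expect_error(nested_comparison(1:6, rep("p1", 6), rep(c("A", "B"), 3)),
               ">= 2 patients")
})

test_that("BH adjustment reproduces the hand step-up computation", {
  expect_equal(bh_adjust(c(0.01, 0.04, 0.03, 0.005)), c(0.02, 0.04, 0.04, 0.02))
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(0.2), 0.2)
  expect_equal(bh_adjust(rep(1, 5)), rep(1, 5))
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("group ANOVA wrappers return adjusted all-pairs and vs-reference contrasts", {
  set.seed(12)
  g <- rep(c("kidney", "ccRCC", "papillary"), each = 8)
  v <- rnorm(24) + rep(c(0, -1.5, 0.2), each = 8)
  tk <- group_anova(v, g, "tukey")
  expect_equal(nrow(tk), 3)
  expect_lt(attr(tk, "anova_p"), 0.01)
  dn <- group_anova(v, factor(g, levels = c("kidney", "ccRCC", "papillary")), "dunnett")
  expect_equal(nrow(dn), 2)
  expect_lt(dn$p_adj[grepl("ccRCC", dn$contrast)], 0.05)
})
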