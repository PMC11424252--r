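test_that("first-turn acetate labelling is m+2 citrate and [4,5] glutamate", {
  sim <- simulate_tca(tracer_spec("acetate", enrichment = 1),
                      tca_params(n_turns = 1, reductive_fraction = 0))
  expect_equal(sim$mids$citrate, c(0, 0, 1, 0, 0, 0, 0))
  glu <- sim$states$glutamate
  expect_equal(glu$probs[sum(2^(c(4, 5) - 1)) + 1], 1)

  # partial enrichment: support restricted to {m+0, m+2}
  sim2 <- simulate_tca(tracer_spec("acetate", enrichment = 0.22),
                       tca_params(n_turns = 1, reductive_fraction = 0))
  expect_equal(which(sim2$mids$citrate > 1e-12) - 1, c(0, 2))
  expect_equal(as.numeric(glu45_fraction(sim2$states$glutamate)), 1)
})

test_that("citrate m+4 requires a second turn and label retention", {
  p2 <- tca_params(n_turns = 2, turnover = 1, pc_fraction = 0,
                   anaplerosis_unlabelled = 0, reductive_fraction = 0)
  sim <- simulate_tca(tracer_spec("acetate", enrichment = 1), p2)
  expect_gt(sim$mids$citrate[5], 0)

  # turnover = 0: malate-derived label never returns, so no m+4 ever
  p0 <- tca_params(n_turns = 6, turnover = 0, reductive_fraction = 0)
  sim0 <- simulate_tca(tracer_spec("acetate", enrichment = 1), p0)
  expect_equal(sim0$mids$citrate[5], 0)
})

test_that("unlabelled inputs are a fixed point", {
  sim <- simulate_tca(tracer_spec("acetate", enrichment = 0),
                      tca_params(n_turns = 5, pdh_fraction = 0))
  for (m in names(sim$mids)) expect_equal(sim$mids[[m]][1], 1)
})

test_that("first-turn oxidative glutamine labelling concentrates at m+4", {
  sim <- simulate_tca(tracer_spec("glutamine", enrichment = 1),
                      tca_params(n_turns = 1, reductive_fraction = 0,
                                 pdh_fraction = 0))
  for (m in c("succinate", "fumarate", "malate"))
    expect_equal(sim$mids[[m]][5], 1)
  # citrate: the labelled part is all m+4 (oxaloacetate m+4 + unlabelled acetyl)
  cit <- sim$mids$citrate
  expect_equal(which(cit > 1e-12) - 1, c(0, 4))
})

test_that("the reductive branch gives citrate m+5 and malate m+3", {
  akg5 <- ps_delta(5, 1:5, "alpha_kg")
  red <- run_reductive_branch(akg5)
  expect_equal(positional_to_mid(red$citrate), c(0, 0, 0, 0, 0, 1, 0))
  expect_equal(positional_to_mid(red$malate), c(0, 0, 0, 1, 0))
  expect_equal(positional_to_mid(red$acetyl), c(0, 0, 1))

  # unlabelled alpha-KG -> all products unlabelled
  red0 <- run_reductive_branch(ps_delta(5, metabolite = "alpha_kg"))
  for (x in red0) expect_equal(positional_to_mid(x)[1], 1)

  # uniform alpha-KG: product MIDs equal pattern-marginal sums by enumeration
  akg_u <- positional_state(5, rep(1 / 32, 32))
  red_u <- run_reductive_branch(akg_u)
  expect_equal(positional_to_mid(red_u$acetyl), oracle_mid(red_u$acetyl))
  expect_equal(positional_to_mid(red_u$acetyl), c(0.25, 0.5, 0.25))
  expect_error(run_reductive_branch(ps_delta(4)), "5 carbons")
})

test_that("glucose labelling routes through PDH and pyruvate carboxylase", {
  # PDH only: first-turn citrate support within {m+0, m+2}
  sim <- simulate_tca(tracer_spec("glucose", enrichment = 0.4),
                      tca_params(n_turns = 1, pc_fraction = 0,
                                 reductive_fraction = 0))
  expect_true(all(which(sim$mids$citrate > 1e-12) - 1 %in% c(0, 2)))

  # with carboxylation, heavier first-turn isotopologues appear
  simpc <- simulate_tca(tracer_spec("glucose", enrichment = 0.4),
                        tca_params(n_turns = 1, pc_fraction = 0.3,
                                   reductive_fraction = 0))
  expect_gt(sum(simpc$mids$citrate[c(4, 6)]), 0)  # m+3 and m+5
})

test_that("every pool remains a probability vector after every turn", {
  tracers <- list(tracer_spec("glucose"), tracer_spec("acetate"),
                  tracer_spec("glutamine"))
  for (tr in tracers) {
    params <- tca_params(n_turns = 6, dilution = 0.1)
    st <- initial_states(tr, params)
    for (i in 1:6) {
      st <- run_oxidative_turn(st, params, tr)
      for (m in names(st)) {
        expect_true(all(st[[m]]$probs >= 0))
        expect_equal(sum(st[[m]]$probs), 1, tolerance = 1e-12)
      }
    }
    # symmetric pools are reversal-invariant
    for (m in c("succinate", "fumarate")) {
      rev_probs <- ps_map(st[[m]], 4:1)$probs
      expect_equal(st[[m]]$probs, rev_probs, tolerance = 1e-12)
    }
  }
})

test_that("label is conserved through each reaction step", {
  tr <- tracer_spec("acetate", enrichment = 0.5)
  params <- tca_params(n_turns = 3, reductive_fraction = 0)
  st <- initial_states(tr, params)
  for (i in 1:3) st <- run_oxidative_turn(st, params, tr)
  # alpha-KGDH: succinate of the NEXT turn inherits alpha-KG labels minus CO2
  succ <- ps_map(st$alpha_kg, c(2, 3, 4, 5))
  co2 <- expected_labels(st$alpha_kg) - expected_labels(succ)
  expect_gte(co2, 0)
  expect_equal(expected_labels(ps_scramble(succ)), expected_labels(succ))
  # condensation adds the two pools' expectations exactly
  cit <- condense(st$oaa, st$acetyl_coa)
  expect_equal(expected_labels(cit),
               expected_labels(st$oaa) + expected_labels(st$acetyl_coa))
})

test_that("labelling ratios respond monotonically to their driving fluxes", {
  grid <- seq(0.1, 1, length.out = 10)

  m42 <- vapply(grid, function(tv) {
    sim <- simulate_tca(tracer_spec("acetate"),
                        tca_params(turnover = tv, reductive_fraction = 0))
    sim$mids$citrate[5] / sim$mids$citrate[3]
  }, numeric(1))
  expect_true(all(diff(m42) >= -1e-12))

  m2p3 <- vapply(grid, function(pdh) {
    sim <- simulate_tca(tracer_spec("glucose"),
                        tca_params(pdh_fraction = pdh, reductive_fraction = 0))
    sim$mids$citrate[3] / sim$mids$pyruvate[4]
  }, numeric(1))
  expect_true(all(diff(m2p3) >= -1e-12))

  m5 <- vapply(seq(0, 0.9, length.out = 10), function(rf) {
    sim <- simulate_tca(tracer_spec("glutamine"),
                        tca_params(reductive_fraction = rf))
    sim$mids$citrate[6]
  }, numeric(1))
  expect_true(all(diff(m5) >= -1e-12))
})

test_that("parameter validation rejects out-of-range values", {
  expect_error(tca_params(turnover = 1.2), "\\[0, 1\\]")
  expect_error(tca_params(pc_fraction = 0.7, anaplerosis_unlabelled = 0.5), "<= 1")
  expect_error(tracer_spec("glucose", enrichment = 1.5), "\\[0, 1\\]")
})
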