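#' TCA-cycle simulator parameters
#'
#' Knobs of the discrete-turn label-propagation model. All fractions live in
#' `[0, 1]`.
#'
#' @param acetyl_enrichment fraction of the acetyl-CoA pool carrying the
#'   tracer pattern when acetyl-CoA is the entry point (default 0.22,
#'   mid-range of the 20-25% enrichments typical of acetate infusions).
#' @param pdh_fraction share of acetyl-CoA derived from the (possibly
#'   labelled) pyruvate pool via pyruvate dehydrogenase.
#' @param pc_fraction share of the oxaloacetate inflow supplied by pyruvate
#'   carboxylation.
#' @param anaplerosis_unlabelled share of the oxaloacetate inflow supplied by
#'   unlabelled anaplerotic sources. `pc_fraction + anaplerosis_unlabelled`
#'   must not exceed 1; the remainder is malate-derived.
#' @param turnover per-turn probability that a malate-derived oxaloacetate
#'   molecule re-enters condensation rather than leaving the cycle; governs
#'   multi-turn labelling such as citrate m+4 from acetate.
#' @param reductive_fraction share of the final citrate (and malate) pool
#'   formed by reductive carboxylation of alpha-ketoglutarate.
#' @param glu_exchange per-turn mixing fraction of the glutamate pool with
#'   alpha-ketoglutarate (1 = full equilibration each turn).
#' @param n_turns number of oxidative turns to propagate (default 8; the
#'   state is essentially converged for `turnover < 1`).
#' @param dilution per-turn fraction of each cycle pool exchanged with
#'   unlabelled material.
#' @return a list of class `tca_params`.
#' @export
tca_params <- function(acetyl_enrichment = 0.22,
                       pdh_fraction = 0.75,
                       pc_fraction = 0.10,
                       anaplerosis_unlabelled = 0.20,
                       turnover = 0.90,
                       reductive_fraction = 0.05,
                       glu_exchange = 1.0,
                       n_turns = 8L,
                       dilution = 0.0) {
  p <- list(acetyl_enrichment = acetyl_enrichment, pdh_fraction = pdh_fraction,
            pc_fraction = pc_fraction, anaplerosis_unlabelled = anaplerosis_unlabelled,
            turnover = turnover, reductive_fraction = reductive_fraction,
            glu_exchange = glu_exchange, n_turns = as.integer(n_turns),
            dilution = dilution)
  fr <- unlist(p[setdiff(names(p), "n_turns")])
  if (any(fr < 0 | fr > 1)) stop("tca_params: all fractions must lie in [0, 1]")
  if (p$pc_fraction + p$anaplerosis_unlabelled > 1 + 1e-12)
    stop("tca_params: pc_fraction + anaplerosis_unlabelled must be <= 1")
  if (p$n_turns < 1L) stop("tca_params: n_turns must be >= 1")
  structure(p, class = "tca_params")
}

#' Tracer specification
#'
#' @param tracer one of `"glucose_U13C"`, `"acetate_12_13C2"`,
#'   `"glutamine_U13C"` (the prefixes `"glucose"`, `"acetate"`,
#'   `"glutamine"` are accepted).
#' @param enrichment fraction of the entry pool carrying the tracer pattern:
#'   pyruvate m+3 for glucose, acetyl-CoA m+2 for acetate, glutamine-derived
#'   alpha-KG m+5 for glutamine. `NULL` picks the tracer default (0.20 for
#'   glucose-derived pyruvate, 0.22 for acetate, 0.32 for glutamine, the last
#'   matching the 30-35% plasma glutamine m+5 enrichments seen clinically).
#' @return a list of class `tracer_spec`.
#' @export
tracer_spec <- function(tracer = c("glucose_U13C", "acetate_12_13C2", "glutamine_U13C"),
                        enrichment = NULL) {
  tracer <- match.arg(sub("^glucose$", "glucose_U13C",
                      sub("^acetate$", "acetate_12_13C2",
                      sub("^glutamine$", "glutamine_U13C", tracer[1]))),
                      c("glucose_U13C", "acetate_12_13C2", "glutamine_U13C"))
  if (is.null(enrichment))
    enrichment <- switch(tracer, glucose_U13C = 0.20, acetate_12_13C2 = 0.22,
                         glutamine_U13C = 0.32)
  if (enrichment < 0 || enrichment > 1) stop("tracer enrichment must lie in [0, 1]")
  structure(list(tracer = tracer, enrichment = enrichment), class = "tracer_spec")
}

# Atom maps (target carbon <- source carbon; 0 = new unlabelled carbon).
# Citrate carbons 1-4 are the OAA carbons, 5 the acetyl carboxyl, 6 the
# acetyl methyl. IDH releases OAA C4; alpha-KGDH releases alpha-KG C1
# (OAA C1). The acetyl carbons therefore land on alpha-KG / glutamate
# carbons 4 (methyl) and 5 (carboxyl), the positional anchor of first-turn
# [4,5-13C]glutamate from [1,2-13C]acetyl-CoA.
.map_pdh        <- c(2L, 3L)              # pyruvate -> acetyl (C1 lost as CO2)
.map_pc         <- c(1L, 2L, 3L, 0L)      # pyruvate + CO2 -> OAA
.map_idh        <- c(1L, 2L, 3L, 6L, 5L)  # citrate -> alpha-KG (drop OAA C4)
.map_akgdh      <- c(2L, 3L, 4L, 5L)      # alpha-KG -> succinate (drop C1)
.map_red_cit    <- c(1L, 2L, 3L, 0L, 5L, 4L) # alpha-KG + CO2 -> citrate
.map_red_acetyl <- c(5L, 4L)              # citrate cleavage: acetyl unit
.map_red_oaa    <- c(1L, 2L, 3L, 0L)      # citrate cleavage: OAA part

dilute <- function(state, dilution) {
  if (dilution <= 0) return(state)
  ps_mix(list(state, ps_delta(state$n_carbons, metabolite = state$metabolite)),
         c(1 - dilution, dilution), state$metabolite)
}

entry_states <- function(tracer, params) {
  e <- tracer$enrichment
  pyr0 <- ps_delta(3L, metabolite = "pyruvate")
  if (tracer$tracer == "glucose_U13C") {
    pyruvate <- ps_mix(list(ps_delta(3L, 1:3, "pyruvate"), pyr0), c(e, 1 - e), "pyruvate")
  } else {
    pyruvate <- pyr0
  }
  # acetyl-CoA supply: via PDH from the pyruvate pool, or directly from acetate
  if (tracer$tracer == "acetate_12_13C2") {
    acetyl <- ps_mix(list(ps_delta(2L, 1:2, "acetyl_coa"),
                          ps_delta(2L, metabolite = "acetyl_coa")),
                     c(e, 1 - e), "acetyl_coa")
  } else {
    from_pyr <- ps_map(pyruvate, .map_pdh, "acetyl_coa")
    acetyl <- ps_mix(list(from_pyr, ps_delta(2L, metabolite = "acetyl_coa")),
                     c(params$pdh_fraction, 1 - params$pdh_fraction), "acetyl_coa")
  }
  list(pyruvate = pyruvate, acetyl_coa = acetyl)
}

glutamine_entry <- function(state, enrichment) {
  ps_mix(list(ps_delta(5L, 1:5, state$metabolite), state),
         c(enrichment, 1 - enrichment), state$metabolite)
}

#' Initial pool states for a tracer
#'
#' All cycle pools start unlabelled; the entry pools (pyruvate, acetyl-CoA,
#' and for glutamine infusions the alpha-KG pool) are seeded at the tracer
#' enrichment.
#'
#' @param tracer a `tracer_spec`.
#' @param params a `tca_params`.
#' @return named list of `positional_state` objects.
#' @export
initial_states <- function(tracer, params) {
  st <- list(
    oaa       = ps_delta(4L, metabolite = "oaa"),
    citrate   = ps_delta(6L, metabolite = "citrate"),
    alpha_kg  = ps_delta(5L, metabolite = "alpha_kg"),
    glutamate = ps_delta(5L, metabolite = "glutamate"),
    succinate = ps_delta(4L, metabolite = "succinate"),
    fumarate  = ps_delta(4L, metabolite = "fumarate"),
    malate    = ps_delta(4L, metabolite = "malate")
  )
  st <- c(entry_states(tracer, params), st)
  if (tracer$tracer == "glutamine_U13C")
    st$alpha_kg <- glutamine_entry(st$alpha_kg, tracer$enrichment)
  st
}

#' One oxidative turn of the TCA cycle
#'
#' Propagates the pool states through one discrete turn:
#' alpha-KG -> succinate (decarboxylation at C1, symmetry scrambling) ->
#' fumarate (scrambled) -> malate -> oxaloacetate (mixed with pyruvate-
#' carboxylase inflow and unlabelled anaplerosis according to
#' `pc_fraction`, `anaplerosis_unlabelled` and `turnover`) -> citrate
#' (condensation with the acetyl pool) -> alpha-KG (IDH decarboxylation),
#' followed by glutamine entry (for that tracer), glutamate exchange and
#' per-pool dilution.
#'
#' @param states named list of pool states as from [initial_states()].
#' @param params a `tca_params`.
#' @param tracer the `tracer_spec` driving the entry pools.
#' @return the updated list of states.
#' @export
run_oxidative_turn <- function(states, params, tracer) {
  p <- params
  states$succinate <- ps_scramble(ps_map(states$alpha_kg, .map_akgdh, "succinate"))
  states$fumarate  <- ps_scramble(ps_map(states$succinate, 1:4, "fumarate"))
  states$malate    <- ps_map(states$fumarate, 1:4, "malate")

  oaa_pc  <- ps_map(states$pyruvate, .map_pc, "oaa")
  w_mal   <- (1 - p$pc_fraction - p$anaplerosis_unlabelled) * p$turnover
  w_unlab <- p$anaplerosis_unlabelled +
             (1 - p$pc_fraction - p$anaplerosis_unlabelled) * (1 - p$turnover)
  states$oaa <- ps_mix(list(oaa_pc,
                            ps_map(states$malate, 1:4, "oaa"),
                            ps_delta(4L, metabolite = "oaa")),
                       c(p$pc_fraction, w_mal, w_unlab), "oaa")

  states$citrate  <- condense(states$oaa, states$acetyl_coa)
  akg <- ps_map(states$citrate, .map_idh, "alpha_kg")
  if (tracer$tracer == "glutamine_U13C")
    akg <- glutamine_entry(akg, tracer$enrichment)
  states$alpha_kg <- akg
  states$glutamate <- ps_mix(list(states$alpha_kg, states$glutamate),
                             c(p$glu_exchange, 1 - p$glu_exchange), "glutamate")

  for (m in c("oaa", "citrate", "alpha_kg", "glutamate",
              "succinate", "fumarate", "malate"))
    states[[m]] <- dilute(states[[m]], p$dilution)
  states
}

#' Reductive carboxylation branch
#'
#' Runs alpha-ketoglutarate backwards through IDH: citrate gains one
#' unlabelled CO2-derived carbon; citrate cleavage returns the two-carbon
#' acetyl unit (alpha-KG carbons 4 and 5) and a four-carbon oxaloacetate
#' (alpha-KG carbons 1-3 plus the CO2 carbon), which is reduced to malate.
#' Fully m+5 alpha-KG therefore yields m+5 citrate and m+3 malate, the
#' signature used to detect reductive glutamine metabolism.
#'
#' @param alpha_kg a 5-carbon `positional_state`.
#' @param params a `tca_params` (currently unused beyond validation).
#' @return list with `citrate`, `acetyl`, `oaa`, `malate` states.
#' @export
run_reductive_branch <- function(alpha_kg, params = tca_params()) {
  stopifnot(inherits(alpha_kg, "positional_state"))
  if (alpha_kg$n_carbons != 5L)
    stop("run_reductive_branch: alpha-KG pool must have 5 carbons")
  citrate <- ps_map(alpha_kg, .map_red_cit, "citrate")
  acetyl  <- ps_map(alpha_kg, .map_red_acetyl, "acetyl_coa")
  oaa     <- ps_map(alpha_kg, .map_red_oaa, "oaa")
  malate  <- ps_map(oaa, 1:4, "malate")
  list(citrate = citrate, acetyl = acetyl, oaa = oaa, malate = malate)
}

#' Simulate TCA-cycle labelling under a tracer
#'
#' Runs `n_turns` discrete oxidative turns from unlabelled initial pools with
#' the entry pools held at the tracer enrichment, then mixes the citrate and
#' malate pools with the reductive-carboxylation branch according to
#' `reductive_fraction`. The model is deterministic and exact over the
#' `2^n`-pattern state space of each pool.
#'
#' @param tracer a `tracer_spec` (or a tracer name).
#' @param params a `tca_params`.
#' @return a list with elements `states` (named `positional_state`s) and
#'   `mids` (named list of mass isotopologue distribution vectors, m+0..m+C),
#'   plus the `tracer` and `params` used.
#' @examples
#' sim <- simulate_tca(tracer_spec("acetate", enrichment = 1),
#'                     tca_params(turnover = 1, pc_fraction = 0,
#'                                anaplerosis_unlabelled = 0, n_turns = 2))
#' round(sim$mids$citrate, 3)  # citrate m+4 appears on the second turn
#' @export
simulate_tca <- function(tracer, params = tca_params()) {
  if (is.character(tracer)) tracer <- tracer_spec(tracer)
  stopifnot(inherits(tracer, "tracer_spec"), inherits(params, "tca_params"))
  states <- initial_states(tracer, params)
  for (i in seq_len(params$n_turns))
    states <- run_oxidative_turn(states, params, tracer)

  rf <- params$reductive_fraction
  if (rf > 0) {
    red <- run_reductive_branch(states$alpha_kg, params)
    states$citrate <- ps_mix(list(states$citrate, red$citrate), c(1 - rf, rf), "citrate")
    states$malate  <- ps_mix(list(states$malate, red$malate), c(1 - rf, rf), "malate")
  }
  mids <- lapply(states, positional_to_mid)
  list(states = states, mids = mids, tracer = tracer, params = params)
}
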