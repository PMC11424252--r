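# Independent brute-force oracles used across the suite. These deliberately
# re-derive quantities by enumeration rather than calling the package's own
# computational path.

# MID by explicit popcount over all patterns of a positional state
oracle_mid <- function(state) {
  n <- state$n_carbons
  mid <- numeric(n + 1)
  for (k in 0:(2^n - 1)) {
    pop <- sum(as.integer(intToBits(k))[1:n])
    mid[pop + 1] <- mid[pop + 1] + state$probs[k + 1]
  }
  mid
}

# natural-abundance envelope by exhaustive enumeration over per-atom states
oracle_abundance <- function(counts, isotopes) {
  dists <- list()
  for (el in names(counts)) {
    for (i in seq_len(counts[[el]])) dists[[length(dists) + 1]] <- isotopes[[el]]
  }
  if (!length(dists)) return(1)
  # expand.grid over each atom's shift
  shifts <- lapply(dists, function(d) seq_along(d) - 1)
  grid <- expand.grid(shifts)
  prob <- rep(1, nrow(grid))
  for (j in seq_along(dists)) prob <- prob * dists[[j]][grid[[j]] + 1]
  total <- rowSums(as.matrix(grid))
  out <- numeric(max(total) + 1)
  for (i in seq_len(nrow(grid))) out[total[i] + 1] <- out[total[i] + 1] + prob[i]
  out
}

# hand product-limit estimator
oracle_km <- function(time, event) {
  ts <- sort(unique(time[event == 1]))
  s <- 1
  surv <- numeric(length(ts))
  for (i in seq_along(ts)) {
    n_risk <- sum(time >= ts[i])
    d <- sum(time == ts[i] & event == 1)
    s <- s * (1 - d / n_risk)
    surv[i] <- s
  }
  list(time = ts, surv = surv,
       median = if (any(surv <= 0.5)) ts[which(surv <= 0.5)[1]] else NA_real_)
}

# hand log-rank statistic (observed - expected, hypergeometric variance)
oracle_logrank_stat <- function(time, event, group) {
  g <- as.integer(as.factor(group))
  ts <- sort(unique(time[event == 1]))
  O <- 0; E <- 0; V <- 0
  for (t in ts) {
    at_risk <- time >= t
    n <- sum(at_risk); n1 <- sum(at_risk & g == 1)
    d <- sum(time == t & event == 1)
    d1 <- sum(time == t & event == 1 & g == 1)
    O <- O + d1
    E <- E + d * n1 / n
    if (n > 1) V <- V + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  (O - E)^2 / V
}

# exact permutation p for the log-rank statistic on a 5+5 set
oracle_logrank_perm_p <- function(time, event) {
  obs_groups <- rep(c(1, 2), each = 5)
  stat_obs <- oracle_logrank_stat(time, event, obs_groups)
  combs <- utils::combn(10, 5)
  stats <- apply(combs, 2, function(idx) {
    grp <- rep(2, 10); grp[idx] <- 1
    oracle_logrank_stat(time, event, grp)
  })
  mean(stats >= stat_obs - 1e-12)
}

random_mid <- function(n_carbons) {
  x <- stats::rgamma(n_carbons + 1, shape = 1)
  x / sum(x)
}
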