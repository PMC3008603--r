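# Independent oracles and small fixture builders used across the suite.

# Breslow log partial likelihood by explicit enumeration of risk sets
# (exact for untied data). Deliberately naive: one term per event, risk set
# recomputed each time. This is the brute-force reference the Newton fit is
# checked against.
enumerated_partial_loglik <- function(beta, time, event, x) {
  ll <- 0
  for (i in which(event == 1)) {
    risk <- which(time >= time[i])
    ll <- ll + beta * x[i] - log(sum(exp(beta * x[risk])))
  }
  ll
}

# Maximise the enumerated partial likelihood on a grid + golden-section
# refinement via optimize().
brute_force_cox_beta <- function(time, event, x, interval = c(-10, 10)) {
  stats::optimize(function(b) enumerated_partial_loglik(b, time, event, x),
                  interval = interval, maximum = TRUE, tol = 1e-10)$maximum
}

# Exact upper-tail hypergeometric overlap probability by full enumeration
# of every possible draw of set B from the universe (only viable for tiny
# universes).
enumerated_overlap_tail <- function(universe_size, a, b, k) {
  draws <- utils::combn(universe_size, b)
  hits <- apply(draws, 2L, function(d) sum(d <= a) >= k)
  mean(hits)
}

# Bare two-group log-rank chi-square (tie-corrected hypergeometric
# variance), independent of the package's implementation; used for the
# permutation null.
bare_logrank_chi <- function(times, events, g2) {
  dt <- sort(unique(times[events == 1]))
  obs <- 0; expd <- 0; v <- 0
  for (t in dt) {
    at <- times >= t
    n <- sum(at); n2 <- sum(at & g2)
    d <- sum(times == t & events == 1)
    d2 <- sum(times == t & events == 1 & g2)
    obs <- obs + d2; expd <- expd + d * n2 / n
    if (n > 1) v <- v + d * (n2 / n) * (1 - n2 / n) * (n - d) / (n - 1)
  }
  if (v > 0) (obs - expd)^2 / v else 0
}

# Small untied survival fixture with a binary covariate.
tiny_cox_fixture <- function() {
  list(time = c(1.3, 2.1, 3.4, 4.7, 5.2, 6.9),
       event = c(1L, 1L, 0L, 1L, 1L, 0L),
       x = c(1, 0, 1, 0, 1, 0))
}

# Small log2 expression matrix with named probes/samples.
small_matrix <- function(p = 20, n = 10, seed = 42) {
  set.seed(seed)
  vals <- matrix(rnorm(p * n, 8, 1.5), p, n,
                 dimnames = list(sprintf("P%03d", 1:p), sprintf("S%03d", 1:n)))
  expression_matrix(vals, scale = "log2")
}

# Standard small synthetic cohort used by several tests.
small_cohort <- function(seed = 11, n = 60, probes = 300, informative = 10,
                         effect = 1.2) {
  generate_cohort(sim_config(n_samples = n, n_probes = probes,
                             n_informative = informative,
                             effect_size = effect, seed = seed,
                             n_reference = 20L,
                             fraction_low_intensity = 0.05))
}
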