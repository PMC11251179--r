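# Randomised model generators for property-style tests. Callers control the
# RNG via set.seed(); rejection keeps only models with finite progeny where
# that matters.

# Smallest pairwise gap between net loss rates, relative to their magnitude;
# the distinct-Delta closed forms divide by these gaps, so property tests
# demand well-separated values.
delta_gap <- function(model) {
  d <- sort(as_reduced(model)$Delta)
  if (length(d) < 2L) return(Inf)
  min(diff(d)) / max(abs(d))
}

rand_irreversible_model <- function(N = 5L, distinct_delta = FALSE) {
  repeat {
    m <- compartment_model(
      lambda = runif(N, 0, 0.4),
      s = c(runif(N - 1L, 0, 0.3), 0),
      a = c(runif(N - 1L, 0, 0.3), 0),
      nu = c(runif(N - 1L, 0.2, 0.8), 0),
      xi = 0,
      mu = runif(N, 0.7, 1.5))
    v <- validate_model(m)
    if (!v$progeny_finite) next
    if (distinct_delta && delta_gap(m) < 0.05) next
    return(m)
  }
}

rand_reversible_model <- function(N = 5L) {
  repeat {
    m <- compartment_model(
      lambda = runif(N, 0, 0.4),
      s = c(runif(N - 1L, 0, 0.3), 0),
      a = c(runif(N - 1L, 0, 0.3), 0),
      nu = c(runif(N - 1L, 0.2, 0.8), 0),
      xi = c(0, runif(N - 1L, 0, 0.3)),
      mu = runif(N, 0.7, 1.5))
    if (validate_model(m)$progeny_finite) return(m)
  }
}

# Self-renewal-only models for lifeline statistics (s = a = 0).
rand_lifeline_model <- function(N = 4L, reversible = TRUE) {
  compartment_model(
    lambda = runif(N, 0.1, 0.6),
    nu = c(runif(N - 1L, 0.2, 0.8), 0),
    xi = if (reversible) c(0, runif(N - 1L, 0, 0.4)) else 0,
    mu = runif(N, 0.3, 1.2))
}

# Dense tridiagonal coefficient matrix of the progeny mean system J m = b.
dense_progeny_matrix <- function(model) {
  dr <- derived_rates(model)
  N <- model$N
  J <- diag(dr$Delta, nrow = N)
  if (N > 1L) {
    J[cbind(1:(N - 1L), 2:N)] <- -dr$Lambda
    J[cbind(2:N, 1:(N - 1L))] <- -model$xi[2:N]
  }
  J
}

expect_within_3se <- function(observed_mean, se, expected, label = NULL,
                              floor = 1e-9) {
  expect_lt(abs(observed_mean - expected), 3 * se + floor, label = label)
}
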