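test_that("a cell in the last compartment lives Exp(mu_N)", {
  m <- compartment_model(lambda = c(0.2, 0.4), nu = c(0.5, 0), mu = c(1, 2))
  tau <- mean_lifespan(m)
  expect_equal(tau[2], 1 / 2)
  expect_equal(lifespan_second_moment(m)[2], 2 / 2^2)
  # exponential lifetime: variance equals the squared mean
  one <- compartment_model(lambda = 0.3, mu = 0.8)
  expect_equal(lifespan_second_moment(one) - mean_lifespan(one)^2,
               mean_lifespan(one)^2)
})

test_that("lifeline statistics require self-renewal-only models", {
  bad <- compartment_model(lambda = c(0.1, 0), s = c(0.2, 0),
                           nu = c(0.5, 0), mu = c(1, 1))
  expect_error(mean_lifespan(bad), "self-renewal-only")
  immortal <- compartment_model(lambda = c(0.1, 0.1), nu = c(0.5, 0),
                                mu = c(0, 0))
  expect_error(mean_lifespan(immortal), "never terminates")
  expect_error(
    lifespan_second_moment(
      compartment_model(lambda = c(0, 0), nu = c(0.5, 0), xi = c(0, 0.2),
                        mu = c(1, 1))),
    "irreversible")
})

test_that("division counts are geometric in the last compartment", {
  m <- compartment_model(lambda = c(0.2, 0.7), nu = c(0.5, 0), mu = c(1, 0.7))
  dv <- mean_divisions(m)
  expect_equal(dv$eta[2], 0.7 / 0.7)  # lambda_N / mu_N = 1
  om <- division_count_distribution(m, start = 2, nmax = 300)
  p <- 0.7 / (0.7 + 0.7)
  n <- 0:10
  expect_equal(unname(om[as.character(n)]), p^n * (1 - p), tolerance = 1e-12)

  nodiv <- compartment_model(lambda = rep(0, 3), nu = c(0.3, 0.3, 0),
                             mu = rep(1, 3))
  expect_equal(unname(division_count_distribution(nodiv, 1, 5)["0"]), 1)
})

test_that("irreversible closed forms match the general recursion", {
  set.seed(82)
  for (rep in 1:20) {
    N <- sample(2:6, 1)
    m <- rand_lifeline_model(N, reversible = FALSE)
    hop <- m$nu / (m$mu + m$nu)
    # lifespan
    tau <- mean_lifespan(m)
    tau_closed <- vapply(seq_len(N), function(i) {
      sum(vapply(i:N, function(k) {
        1 / (m$mu[k] + m$nu[k]) * if (k > i) prod(hop[i:(k - 1)]) else 1
      }, numeric(1)))
    }, numeric(1))
    expect_equal(tau, tau_closed, tolerance = 1e-10)
    # death-compartment probabilities
    beta <- death_compartment_probabilities(m)
    for (i in seq_len(N)) {
      expect_equal(beta[i, i], m$mu[i] / (m$mu[i] + m$nu[i]),
                   tolerance = 1e-10)
      if (i < N) for (j in (i + 1):N)
        expect_equal(beta[i, j],
                     m$mu[j] / (m$mu[j] + m$nu[j]) * prod(hop[i:(j - 1)]),
                     tolerance = 1e-10)
    }
    # divisions per compartment
    dv <- mean_divisions(m)
    for (i in seq_len(N)) for (j in i:N) {
      expected <- m$lambda[j] / (m$mu[j] + m$nu[j]) *
        (if (j > i) prod(hop[i:(j - 1)]) else 1)
      expect_equal(dv$eta_by_compartment[i, j], expected, tolerance = 1e-10)
    }
  }
})

test_that("lifeline distributions normalise and reproduce their means", {
  set.seed(92)
  for (rep in 1:10) {
    m <- rand_lifeline_model(sample(2:5, 1), reversible = TRUE)
    beta <- death_compartment_probabilities(m)
    expect_equal(rowSums(beta), rep(1, m$N), ignore_attr = TRUE,
                 tolerance = 1e-10)
    tau <- mean_lifespan(m)
    expect_true(all(tau > 0))
    dv <- mean_divisions(m)
    expect_equal(rowSums(dv$eta_by_compartment), dv$eta,
                 ignore_attr = TRUE, tolerance = 1e-10)
    om <- division_count_distribution(m, 1, nmax = 400)
    expect_true(all(om >= 0))
    expect_lt(attr(om, "tail_mass"), 1e-10)
    expect_equal(sum(as.numeric(names(om)) * om), dv$eta[1],
                 tolerance = 1e-8)
  }
  # second moment dominates the squared mean
  set.seed(93)
  m <- rand_lifeline_model(4L, reversible = FALSE)
  expect_true(all(lifespan_second_moment(m) >= mean_lifespan(m)^2))
})

test_that("simulated lifelines reproduce the analytic statistics", {
  set.seed(102)
  m <- rand_lifeline_model(4L, reversible = TRUE)
  R <- 20000L
  sims <- simulate_lifelines(m, start = 1, replicates = R, seed = 5)
  tau <- mean_lifespan(m)
  expect_within_3se(mean(sims$T), stats::sd(sims$T) / sqrt(R), tau[1])
  dv <- mean_divisions(m)
  expect_within_3se(mean(sims$D), stats::sd(sims$D) / sqrt(R), dv$eta[1])
  beta <- death_compartment_probabilities(m)
  for (j in seq_len(m$N)) {
    p_hat <- mean(sims$death_compartment == j)
    se <- sqrt(beta[1, j] * (1 - beta[1, j]) / R)
    expect_within_3se(p_hat, se, beta[1, j])
  }
  # division-count histogram: chi-square goodness of fit at 1%
  om <- division_count_distribution(m, 1, nmax = 400)
  kcut <- max(sims$D)
  probs <- c(om[as.character(0:kcut)],
             1 - sum(om[as.character(0:kcut)]))
  counts <- c(tabulate(sims$D + 1L, nbins = kcut + 1L), 0L)
  keep <- probs * R >= 5
  gof <- suppressWarnings(
    stats::chisq.test(c(counts[keep], sum(counts[!keep])),
                      p = c(probs[keep], sum(probs[!keep]))))
  expect_gt(gof$p.value, 0.01)
})

test_that("elasticity behaves as a normalised derivative", {
  # power law f = theta^2 has elasticity 2 everywhere
  m <- compartment_model(lambda = c(0.2, 0), nu = c(0.5, 0), mu = c(1, 1))
  expect_equal(elasticity(function(mm) mm$mu[1]^2, m, "mu", 1), 2,
               tolerance = 1e-8)
  # a parameter the statistic does not involve
  expect_equal(elasticity(function(mm) mm$mu[1]^2, m, "nu", 1), 0)
  # theta = 0: sensitivity only, flagged
  s0 <- elasticity(function(mm) mm$lambda[2] + 1, m, "lambda", 2)
  expect_true(attr(s0, "sensitivity_only"))
  expect_equal(as.numeric(s0), 1, tolerance = 1e-6)
  # f = 0 at the base point is an error carrying the raw sensitivity
  err <- tryCatch(elasticity(function(mm) mm$mu[1] - 1, m, "mu", 1),
                  error = identity)
  expect_s3_class(err, "error")
  expect_equal(err$sensitivity, 1, tolerance = 1e-6)
})
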