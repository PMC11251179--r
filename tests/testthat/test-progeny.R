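test_that("terminal-compartment progeny mean has the closed form", {
  m <- compartment_model(lambda = c(0, 0.3), nu = c(0.5, 0), mu = c(1, 0.9))
  expect_equal(mean_total_progeny(m)[2], 2 * 0.3 / (0.9 - 0.3))  # = 1
  expect_equal(mean_progeny_by_compartment(m)[2, 2],
               2 * 0.3 / derived_rates(m)$Delta[2])
})

test_that("no divisions means no progeny", {
  m <- compartment_model(lambda = rep(0, 4), nu = c(0.4, 0.4, 0.4, 0),
                         mu = rep(1, 4))
  expect_equal(mean_total_progeny(m), rep(0, 4))
  expect_equal(unname(mean_progeny_by_compartment(m)), matrix(0, 4, 4))
})

test_that("the tridiagonal recursion reproduces a dense linear solve", {
  set.seed(52)
  for (rep in 1:100) {
    m <- rand_reversible_model(sample(2:7, 1))
    b <- with(m, 2 * (lambda + a + s))
    dense <- solve(dense_progeny_matrix(m), b)
    expect_equal(mean_total_progeny(m), dense, tolerance = 1e-10)
  }
})

test_that("progeny means decompose consistently over birth compartments", {
  set.seed(62)
  for (rep in 1:25) {
    m <- if (rep %% 2) rand_reversible_model(sample(2:6, 1))
         else rand_irreversible_model(sample(2:6, 1))
    mj <- mean_progeny_by_compartment(m)
    expect_equal(rowSums(mj), mean_total_progeny(m),
                 ignore_attr = TRUE, tolerance = 1e-10)
    expect_true(all(mj >= 0))
    if (is_irreversible(m))
      expect_true(all(mj[lower.tri(mj)] == 0))
  }
})

test_that("self-renewal-only progeny decays along the chain", {
  only_sr <- load_case_study("four_comp_only_SR")
  mj <- mean_progeny_by_compartment(only_sr)
  expect_equal(mj[1, 4], 0)  # nothing is *born* into C4 without s or a
  expect_true(mj[1, 1] > mj[1, 2])
  expect_true(mj[1, 2] > mj[1, 3])
  # simulation oracle for the first row
  sims <- simulate_progenies(only_sr, 1, replicates = 4000, seed = 19)
  se <- apply(sims[paste0("G", 1:4)], 2, stats::sd) / sqrt(nrow(sims))
  for (j in 1:4)
    expect_within_3se(mean(sims[[paste0("G", j)]]), se[j], mj[1, j])
})

test_that("infinite progeny is reported with the violated condition", {
  hot <- compartment_model(lambda = c(1.5, 0.1), nu = c(0.2, 0),
                           mu = c(0.3, 0.9))  # Delta_1 < 0
  expect_error(mean_total_progeny(hot), "Delta_1 > 0")
  expect_error(mean_progeny_by_compartment(hot), "finiteness")
  expect_error(mean_total_progeny(load_case_study("hsc_table1")),
               "reduced")
})

test_that("terminal birth-death progeny follows the Catalan series", {
  pg <- last_compartment_progeny_distribution(0.3, 0.9, kmax = 400)
  pd <- 0.75; pb <- 0.25
  expect_equal(pg$pd, pd)
  expect_equal(unname(pg$probs[c("0", "2", "4")]),
               c(pd, pd^2 * pb, 2 * pd^3 * pb^2))
  expect_equal(unname(pg$probs[seq(2, 400, by = 2)]), rep(0, 200))
  # subcritical: mass sums to one and the mean matches 2 lambda/(mu - lambda)
  expect_lt(pg$tail_mass, 1e-6)
  k <- as.numeric(names(pg$probs))
  expect_equal(sum(k * pg$probs), 2 * 0.3 / (0.9 - 0.3), tolerance = 1e-6)

  expect_equal(unname(last_compartment_progeny_distribution(0, 1, 10)$probs[1]), 1)

  # successive even-order probabilities follow the Catalan ratio
  # C_{n+1}/C_n * pd * pb = 2(2n+1)/(n+2) * pd * pb
  n <- 0:20
  ratio <- unname(pg$probs[as.character(2 * n + 2)] /
                    pg$probs[as.character(2 * n)])
  expect_equal(ratio, 2 * (2 * n + 1) / (n + 2) * pd * pb, tolerance = 1e-12)
})

test_that("contour inversion of the pgf matches the Catalan closed form", {
  m <- compartment_model(lambda = c(0.1, 0.3), nu = c(0.5, 0), mu = c(1, 0.9))
  inv <- progeny_distribution_irreversible(m, start = 2, kmax = 120)
  cat_series <- last_compartment_progeny_distribution(0.3, 0.9, kmax = 120)
  expect_equal(unname(inv$probs), unname(cat_series$probs), tolerance = 1e-8)
})

test_that("the pgf derivative at one recovers the progeny mean", {
  set.seed(72)
  for (rep in 1:5) {
    m <- rand_irreversible_model(sample(2:5, 1))
    mexp <- mean_total_progeny(m)
    # one-sided finite difference of Phi_start at z -> 1^-
    h <- 1e-6
    for (start in c(1L, m$N)) {
      phi <- vapply(c(1 - 2 * h, 1 - h),
                    function(z) Re(cellchains:::.pgf_eval(m, start, z + 0i)$phi),
                    numeric(1))
      slope <- (phi[2] - phi[1]) / h
      expect_equal(slope, mexp[start], tolerance = 1e-3)
    }
    # the first-derivative recursion of the generating functions, solved
    # backwards, must reproduce the tridiagonal-system means exactly
    dr <- derived_rates(m)
    rec <- numeric(m$N)
    rec[m$N] <- 2 * m$lambda[m$N] / dr$Delta[m$N]
    if (m$N > 1L) for (i in (m$N - 1L):1L)
      rec[i] <- (2 * (m$a[i] + m$lambda[i] + m$s[i]) +
                   dr$Lambda[i] * rec[i + 1L]) / dr$Delta[i]
    expect_equal(rec, mexp, tolerance = 1e-12)
  }
})

test_that("pgf-derived distributions agree with progeny simulations", {
  m <- load_case_study("four_comp_dom_SD")
  inv <- progeny_distribution_irreversible(m, start = 1, kmax = 150)
  expect_gte(min(inv$probs), 0)
  expect_lt(inv$tail_mass, 1e-4)
  k <- as.numeric(names(inv$probs))
  dist_mean <- sum(k * inv$probs)
  expect_equal(dist_mean, mean_total_progeny(m)[1], tolerance = 1e-3)
  sims <- simulate_progenies(m, 1, replicates = 4000, seed = 23)
  se <- stats::sd(sims$G) / sqrt(nrow(sims))
  expect_within_3se(mean(sims$G), se, dist_mean)
})

test_that("the pgf route refuses reversible chains", {
  m <- compartment_model(lambda = c(0.1, 0.1), nu = c(0.5, 0),
                         xi = c(0, 0.2), mu = c(1, 1))
  expect_error(progeny_distribution_irreversible(m, 1, 50), "irreversible")
})
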