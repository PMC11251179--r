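test_that("the generator is the expected tridiagonal matrix", {
  m1 <- compartment_model(lambda = 0.3, mu = 0.8)
  expect_equal(build_generator(m1), matrix(0.3 - 0.8))

  A <- build_generator(load_case_study("four_comp_only_SR"))
  expect_equal(diag(A), c(-0.6, -0.6, -0.6, 0))
  expect_equal(A[cbind(2:4, 1:3)], rep(0.5, 3))
  expect_equal(A[upper.tri(A)], rep(0, 6))

  hsc <- load_case_study("hsc_table1")
  Ah <- build_generator(hsc)
  expect_equal(diag(Ah), -hsc$Delta)
  expect_equal(Ah[cbind(2:5, 1:4)], hsc$Lambda)
})

test_that("matrix-exponential solution handles constant and growing chains", {
  zero <- compartment_model(lambda = rep(0, 3), mu = rep(0, 3))
  tr <- solve_mean_matrix_exp(zero, c(2, 5, 1), c(0, 1, 10))
  expect_equal(tr$values, matrix(rep(c(2, 5, 1), each = 3), 3, 3),
               ignore_attr = TRUE)

  # the HSC chain has Delta_1 < 0: unbounded late-time growth of C_1
  hsc <- load_case_study("hsc_table1")
  tr <- solve_mean_matrix_exp(hsc, c(890, 1370, 1540, 2020, 1.5e4),
                              seq(0, 1500, by = 250))
  expect_equal(tr$values[1, ], c(890, 1370, 1540, 2020, 1.5e4),
               ignore_attr = TRUE)
  late_c1 <- tr$values[4:7, 1]
  expect_true(all(diff(late_c1) > 0))
})

test_that("closed forms agree with the matrix exponential", {
  times <- c(0, 0.1, 1, 10)
  # pairwise-distinct net loss rates
  set.seed(21)
  for (rep in 1:10) {
    m <- rand_irreversible_model(sample(2:6, 1), distinct_delta = TRUE)
    cf <- mean_irreversible_closed_form(m, times)
    expect_identical(cf$method, "closed_form_distinct")
    me <- solve_mean_matrix_exp(m, cf$C0, times)
    expect_equal(cf$values, me$values, tolerance = 1e-8)
  }
  # all-equal net loss rates: gamma-shaped profile Lambda^(i-1) t^(i-1) e^(-Delta t)/(i-1)!
  eq <- compartment_model(lambda = rep(0.2, 4), nu = rep_len(c(0.5, 0.5, 0.5, 0), 4),
                          mu = c(0.7, 0.7, 0.7, 1.2))
  dr <- derived_rates(eq)
  expect_equal(length(unique(dr$Delta)), 1L)
  cf <- mean_irreversible_closed_form(eq, times)
  expect_identical(cf$method, "closed_form_equal")
  expect_equal(cf$values[, 3],
               dr$Lambda[1] * dr$Lambda[2] * times^2 / 2 *
                 exp(-dr$Delta[3] * times))
  me <- solve_mean_matrix_exp(eq, cf$C0, times)
  expect_equal(cf$values, me$values, tolerance = 1e-8)

  # accumulating terminal compartment with equal upstream Delta:
  # complementary form for E[C_N]
  only_sr <- load_case_study("four_comp_only_SR")
  cf <- mean_irreversible_closed_form(only_sr, times)
  me <- solve_mean_matrix_exp(only_sr, cf$C0, times)
  expect_equal(cf$values, me$values, tolerance = 1e-8)
  expect_equal(cf$values[, 3], 0.5^2 * times^2 / 2 * exp(-0.6 * times))

  # mixed multiplicity falls back to the matrix exponential, with a notice
  mixed <- reduced_model(Delta = c(0.5, 0.5, 0.9), Lambda = c(0.3, 0.3))
  expect_message(cf <- mean_irreversible_closed_form(mixed, times), "mixed")
  expect_identical(cf$method, "matrix_exponential")

  expect_error(
    mean_irreversible_closed_form(
      compartment_model(lambda = c(0, 0), mu = c(1, 1), xi = c(0, 0.2))),
    "irreversible")
})

test_that("terminal accumulation reaches the product-form limit", {
  only_sr <- load_case_study("four_comp_only_SR")
  expect_equal(terminal_limit(only_sr), (0.5 / 0.6)^3)
  # oracle: matrix exponential at a late time from one progenitor
  late <- unname(solve_mean_matrix_exp(only_sr, c(1, 0, 0, 0), 200)$values[1, 4])
  expect_equal(terminal_limit(only_sr), late, tolerance = 1e-4)

  # conserved flux: Lambda_i = Delta_i in every transit compartment
  cons <- reduced_model(Delta = c(0.4, 0.7, 0), Lambda = c(0.4, 0.7))
  expect_equal(terminal_limit(cons), 1)

  # symmetric division boosts the terminal yield
  dom_sd <- load_case_study("four_comp_dom_SD")
  expect_equal(terminal_limit(dom_sd), (2.03 / 2.13)^3)
  expect_gt(terminal_limit(dom_sd), terminal_limit(only_sr))
  late_sd <- unname(solve_mean_matrix_exp(dom_sd, c(1, 0, 0, 0), 200)$values[1, 4])
  expect_equal(terminal_limit(dom_sd), late_sd, tolerance = 1e-6)

  expect_error(terminal_limit(load_case_study("hsc_table1")),
               "accumulating")
})

test_that("stability is governed by the generator spectrum", {
  set.seed(31)
  m <- rand_irreversible_model(5L, distinct_delta = TRUE)
  st <- assess_stability(m)
  ev <- sort(Re(eigen(build_generator(m), only.values = TRUE)$values))
  expect_equal(ev, sort(-derived_rates(m)$Delta), tolerance = 1e-10)
  expect_true(st$stable)

  expect_false(assess_stability(load_case_study("hsc_table1"))$stable)

  deaths <- compartment_model(lambda = rep(0, 3), mu = c(0.2, 1, 0.4))
  expect_true(assess_stability(deaths)$stable)
})

test_that("an accumulating terminal compartment is monotone in time", {
  set.seed(41)
  for (rep in 1:5) {
    N <- sample(3:5, 1)
    m <- rand_irreversible_model(N)
    m$mu[N] <- 0; m$lambda[N] <- 0   # make the last compartment inert
    tr <- solve_mean_matrix_exp(m, c(1, rep(0, N - 1)),
                                seq(0, 50, length.out = 60))
    expect_true(all(diff(tr$values[, N]) > -1e-10))
  }
})
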