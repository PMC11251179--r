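# Single-cell lifeline statistics.
#
# When all divisions are self-renewals (s = a = 0), one daughter of each
# division can be identified with the mother, so a single-cell "lifeline"
# through the chain is well defined: a CTMC over {C_1, ..., C_N, death}.
# Its lifespan, division counts and death-compartment probabilities satisfy
# first-step tridiagonal systems sharing one elimination/substitution
# backbone, with diagonal DeltaBar_i = mu_i + nu_i + xi_i (or
# DeltaHat_i = mu_i + lambda_i + nu_i + xi_i for the division-count
# distribution, where division is itself an event of the embedded chain).

.require_lifeline_model <- function(model) {
  .require_full_model(model, "lifeline statistics")
  if (any(model$s > 0) || any(model$a > 0))
    stop("lifeline statistics are defined for self-renewal-only models ",
         "(s = a = 0): with symmetric or asymmetric division the ",
         "continuation daughter is ill-defined")
  if (all(model$mu == 0))
    stop("all death rates are zero: the lifeline never terminates")
}

# Solve diag_i x_i = nu_i x_{i+1} + xi_i x_{i-1} + src_i with x_0 = x_{N+1}
# implicitly absent; `src` may be a vector or an N x m matrix (column-wise).
.lifeline_solve <- function(diagv, nu, xi, src) {
  src <- as.matrix(src)
  N <- length(diagv)
  gamma <- numeric(N)
  rho <- matrix(0, N, ncol(src))
  gamma_prev <- 0; rho_prev <- rep(0, ncol(src))
  for (i in seq_len(N)) {
    piv <- diagv[i] + xi[i] * gamma_prev
    if (piv <= 0)
      stop(sprintf(
        "lifeline first-step system is singular at compartment %d (pivot %g): the tracked cell is not absorbed almost surely",
        i, piv))
    rho[i, ] <- (src[i, ] + xi[i] * rho_prev) / piv
    gamma[i] <- if (i < N) -nu[i] / piv else 0
    gamma_prev <- gamma[i]; rho_prev <- rho[i, ]
  }
  x <- matrix(0, N, ncol(src))
  x[N, ] <- rho[N, ]
  if (N > 1L) for (i in (N - 1L):1L) x[i, ] <- rho[i, ] - gamma[i] * x[i + 1L, ]
  x
}

#' Mean lifespan of a tracked cell
#'
#' \eqn{\tau_i = E[T_i]}, the mean time until a lifeline started in
#' \eqn{C_i} terminates with a death event. Self-renewal does not change the
#' tracked cell's compartment, so the lifespan involves only \eqn{\mu},
#' \eqn{\nu} and \eqn{\xi}. For a cell starting in the last compartment
#' \eqn{T_N \sim Exp(\mu_N)} (when \eqn{\xi_N = 0}).
#'
#' @param model a \code{compartment_model} with \code{s = a = 0}.
#' @return Numeric vector \eqn{\tau} of length \code{N} (model time units).
#' @export
mean_lifespan <- function(model) {
  .require_lifeline_model(model)
  dr <- derived_rates(model)
  as.numeric(.lifeline_solve(dr$DeltaBar, model$nu, model$xi,
                             rep(1, model$N)))
}

#' Second moment of the lifeline lifespan (irreversible model)
#'
#' \eqn{E[T_i^2]} for the irreversible model, via the closed recursion
#' \eqn{E[T_i^2] = \sum_{j \ge i} R_j \prod_{r=i}^{j-1} \nu_r/(\mu_r+\nu_r)}
#' with \eqn{R_i = 2(\nu_i \tau_{i+1} + 1)/(\mu_i + \nu_i)^2} and
#' \eqn{R_N = 2/\mu_N^2}. The general reversible second moment requires
#' transform inversion and is not provided.
#'
#' @param model an irreversible \code{compartment_model} with
#'   \code{s = a = 0}.
#' @return Numeric vector of second moments, length \code{N}.
#' @export
lifespan_second_moment <- function(model) {
  .require_lifeline_model(model)
  if (!is_irreversible(model))
    stop("the closed second moment is available for the irreversible model only")
  N <- model$N
  if (model$mu[N] <= 0)
    stop("mu_N must be positive (cells reaching the last compartment must die)")
  tau <- mean_lifespan(model)
  hop <- with(model, nu / (mu + nu))         # P(move on before dying)
  R <- numeric(N)
  if (N > 1L)
    R[-N] <- with(model,
                  2 * (nu[-N] * tau[-1L] + 1) / (mu[-N] + nu[-N])^2)
  R[N] <- 2 / model$mu[N]^2
  vapply(seq_len(N), function(i) {
    sum(vapply(i:N, function(j) {
      R[j] * if (j > i) prod(hop[i:(j - 1L)]) else 1
    }, numeric(1)))
  }, numeric(1))
}

#' Mean number of divisions along a lifeline
#'
#' \eqn{\eta_i = E[D_i]}, the mean number of self-renewal divisions along a
#' lifeline started in \eqn{C_i}, together with its split
#' \eqn{\eta_i(j) = E[D_i(j)]} by the compartment in which each division
#' occurs. The totals satisfy the first-step system with source
#' \eqn{\lambda_i}; each per-compartment column solves the same system with
#' source \eqn{\lambda_i 1_{i=j}}, so \eqn{\eta_i = \sum_j \eta_i(j)} holds
#' by linearity. In the irreversible model
#' \eqn{\eta_N = \lambda_N / \mu_N} (\eqn{D_N} is geometric).
#'
#' @param model a \code{compartment_model} with \code{s = a = 0}.
#' @return List with \code{eta} (length \code{N}) and
#'   \code{eta_by_compartment} (\code{N x N}, rows = start compartment).
#' @export
mean_divisions <- function(model) {
  .require_lifeline_model(model)
  dr <- derived_rates(model)
  N <- model$N
  src <- diag(model$lambda, nrow = N)
  byc <- .lifeline_solve(dr$DeltaBar, model$nu, model$xi, src)
  dimnames(byc) <- list(start = paste0("C", 1:N), in_comp = paste0("C", 1:N))
  list(eta = unname(rowSums(byc)), eta_by_compartment = byc)
}

#' Distribution of the number of divisions along a lifeline
#'
#' \eqn{\omega_i(n) = P(D_i = n)}. Because a division is itself an event of
#' the embedded jump chain, the first-step system uses the total exit rate
#' \eqn{\hat\Delta_i = \mu_i + \lambda_i + \nu_i + \xi_i} and couples
#' \eqn{\omega_i(n)} to \eqn{\omega_i(n-1)}: the recursion is run jointly
#' over all start compartments for increasing \eqn{n}
#' (\eqn{\omega_i(-1) = 0}).
#'
#' @param model a \code{compartment_model} with \code{s = a = 0}.
#' @param start start compartment.
#' @param nmax largest division count evaluated (default 200).
#' @param tail_tol warn when more than this much mass lies beyond
#'   \code{nmax}.
#' @return Numeric vector \eqn{\omega_{start}(0..nmax)} with attribute
#'   \code{tail_mass}; the full \code{N x (nmax+1)} table is attached as
#'   attribute \code{omega_all}.
#' @export
division_count_distribution <- function(model, start = 1L, nmax = 200L,
                                        tail_tol = 1e-8) {
  .require_lifeline_model(model)
  N <- model$N
  stopifnot(start >= 1L, start <= N, nmax >= 0L)
  dr <- derived_rates(model)
  omega <- matrix(0, N, nmax + 1L,
                  dimnames = list(start = paste0("C", 1:N), n = 0:nmax))
  prev <- rep(0, N)                     # omega_i(-1)
  for (n in 0:nmax) {
    src <- model$lambda * prev + model$mu * (n == 0)
    omega[, n + 1L] <- .lifeline_solve(dr$DeltaHat, model$nu, model$xi, src)
    prev <- omega[, n + 1L]
  }
  tails <- 1 - rowSums(omega)
  if (tails[start] > tail_tol)
    warning(sprintf(
      "%.3g of the division-count mass lies beyond nmax = %d; increase nmax",
      tails[start], nmax))
  out <- omega[start, ]
  attr(out, "tail_mass") <- max(0, tails[start])
  attr(out, "omega_all") <- omega
  out
}

#' Death-compartment probabilities of a lifeline
#'
#' \eqn{\beta_i(j)}, the probability that a lifeline started in \eqn{C_i}
#' terminates with a death event while in compartment \eqn{C_j}. Rows sum to
#' one whenever every compartment has a positive death rate or death is
#' otherwise certain. In the irreversible model
#' \eqn{\beta_i(i) = \mu_i / (\mu_i + \nu_i)} and
#' \eqn{\beta_i(j) = \mu_j/(\mu_j+\nu_j) \prod_{k=i}^{j-1}
#' \nu_k/(\mu_k+\nu_k)} for \eqn{j > i}.
#'
#' @param model a \code{compartment_model} with \code{s = a = 0}.
#' @return An \code{N x N} matrix, rows = start compartment, columns = death
#'   compartment.
#' @export
death_compartment_probabilities <- function(model) {
  .require_lifeline_model(model)
  dr <- derived_rates(model)
  N <- model$N
  src <- diag(model$mu, nrow = N)
  beta <- .lifeline_solve(dr$DeltaBar, model$nu, model$xi, src)
  dimnames(beta) <- list(start = paste0("C", 1:N),
                         dies_in = paste0("C", 1:N))
  beta
}

#' Elasticity of a model statistic with respect to one rate
#'
#' Computes the local elasticity
#' \eqn{(\partial f/\partial \theta) \cdot \theta / f} of a scalar statistic
#' \eqn{f(model)} with respect to a single rate entry, by central finite
#' differences with a relative step.
#'
#' @param stat_fn function mapping a model to a scalar.
#' @param model a \code{compartment_model} (or any model whose rate fields
#'   are numeric vectors, e.g. a \code{thymic_model}).
#' @param param name of the rate field (e.g. \code{"mu"}).
#' @param index compartment index within that field (default 1, for scalar
#'   fields).
#' @param rel_step relative finite-difference step (default \code{1e-6}).
#' @return The elasticity, a scalar. If \eqn{\theta = 0} the elasticity is
#'   undefined: the raw sensitivity \eqn{\partial f/\partial \theta} (by a
#'   one-sided absolute step) is returned instead, carrying attribute
#'   \code{sensitivity_only = TRUE}. If \eqn{f = 0} at the base point an
#'   error is raised with the raw sensitivity attached as a condition field.
#' @examples
#' m <- load_case_study("four_comp_only_SR")
#' elasticity(function(x) mean_total_progeny(x)[1], m, "lambda", 1)
#' @export
elasticity <- function(stat_fn, model, param, index = 1L, rel_step = 1e-6) {
  theta <- model[[param]][index]
  if (is.null(theta) || is.na(theta))
    stop(sprintf("model has no rate `%s[%d]`", param, index))
  perturb <- function(value) {
    m2 <- model
    m2[[param]][index] <- value
    stat_fn(m2)
  }
  if (theta == 0) {
    h <- rel_step
    sens <- (perturb(h) - perturb(0)) / h
    return(structure(sens, sensitivity_only = TRUE))
  }
  h <- abs(theta) * rel_step
  f_plus <- perturb(theta + h)
  f_minus <- perturb(theta - h)
  sens <- (f_plus - f_minus) / (2 * h)
  f0 <- stat_fn(model)
  if (f0 == 0) {
    cond <- simpleError(sprintf(
      "elasticity undefined: statistic is zero at the base point (sensitivity = %g)",
      sens))
    cond$sensitivity <- sens
    stop(cond)
  }
  sens * theta / f0
}
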