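# Progeny-size distributions via probability generating functions.
#
# The terminal compartment is a linear birth-death process whose total
# progeny pgf has the Catalan closed form; upstream compartments satisfy a
# per-compartment quadratic functional equation solved backwards along the
# chain, and probabilities are recovered by discrete-Fourier (Cauchy contour)
# inversion of the power series.

new_pgf_series <- function(start, probs, tail_mass, pd = NA_real_,
                           pb = NA_real_) {
  names(probs) <- 0:(length(probs) - 1L)
  structure(list(start = start, probs = probs, tail_mass = tail_mass,
                 pd = pd, pb = pb),
            class = "pgf_series")
}

#' @export
print.pgf_series <- function(x, ...) {
  cat(sprintf("Progeny-size distribution from compartment %s (k = 0..%d)\n",
              x$start, length(x$probs) - 1L))
  k <- which(x$probs > 0)
  show <- utils::head(k, 8L)
  print(signif(x$probs[show], 6))
  cat(sprintf("tail mass beyond kmax: %.3g\n", x$tail_mass))
  invisible(x)
}

#' Progeny distribution of the terminal birth-death compartment
#'
#' A cell in the last compartment can only self-renew (rate \eqn{\lambda_N})
#' or die (rate \eqn{\mu_N}); its total progeny is that of a linear
#' birth-death process with discrete birth/death probabilities
#' \eqn{p_b = \lambda_N / (\lambda_N + \mu_N)},
#' \eqn{p_d = \mu_N / (\lambda_N + \mu_N)}. The progeny size is even with
#' \eqn{P(G_N = 2n) = C_n p_d^{n+1} p_b^n}, where \eqn{C_n} is the n-th
#' Catalan number; terms are evaluated in log space so that large \eqn{n}
#' does not overflow the factorials.
#'
#' @param lambda_N,mu_N terminal self-renewal and death rates
#'   (\code{mu_N + lambda_N > 0}).
#' @param kmax largest progeny size evaluated.
#' @return A \code{pgf_series} with fields \code{probs} (for
#'   \eqn{k = 0..kmax}), \code{tail_mass}, \code{pd}, \code{pb}. In the
#'   supercritical case \eqn{\lambda_N > \mu_N} the distribution is
#'   defective and the tail mass includes the probability of an infinite
#'   progeny.
#' @export
last_compartment_progeny_distribution <- function(lambda_N, mu_N, kmax = 200) {
  stopifnot(lambda_N >= 0, mu_N >= 0, kmax >= 0)
  if (lambda_N + mu_N == 0)
    stop("lambda_N + mu_N must be positive")
  pd <- mu_N / (mu_N + lambda_N)
  pb <- lambda_N / (mu_N + lambda_N)
  probs <- numeric(kmax + 1L)
  n <- 0:(kmax %/% 2L)
  if (pb == 0) {
    probs[1L] <- 1        # no divisions possible
  } else {
    log_catalan <- lgamma(2 * n + 1) - lgamma(n + 2) - lgamma(n + 1)
    probs[2L * n + 1L] <- exp(log_catalan + (n + 1) * log(pd) + n * log(pb))
  }
  new_pgf_series("N", probs, tail_mass = max(0, 1 - sum(probs)),
                 pd = pd, pb = pb)
}

# Evaluate Phi_i(z) for i = start..N at complex points z (|z| <= 1).
# Phi_N has the stable closed form 2 p_d / (1 + sqrt(1 - 4 x)),
# x = p_d p_b z^2; upstream compartments solve
#   lambda z^2 Phi^2 + (a z^2 Phi_next - Sigma) Phi
#     + Phi_next (nu + s z^2 Phi_next) + mu = 0
# taking the root that is analytic in the unit disk (the minimal root,
# evaluated in the numerically stable form 2C / (-B + sqrt(B^2 - 4AC))).
.pgf_eval <- function(model, start, z) {
  dr <- derived_rates(model)
  N <- model$N
  if (model$mu[N] + model$lambda[N] == 0) {
    if (!.inert_compartments(model)[N])
      stop("terminal compartment needs mu_N + lambda_N > 0 for the pgf")
    # inert terminal compartment: cells there do nothing, so G_N = 0 a.s.
    pd <- 1; pb <- 0
    phi <- rep(1 + 0i, length(z))
  } else {
    pd <- model$mu[N] / (model$mu[N] + model$lambda[N])
    pb <- model$lambda[N] / (model$mu[N] + model$lambda[N])
    x <- pd * pb * z^2
    phi <- 2 * pd / (1 + sqrt(1 - 4 * x))
  }
  if (start < N) for (i in (N - 1L):start) {
    A <- model$lambda[i] * z^2
    B <- model$a[i] * z^2 * phi - dr$Sigma[i]
    C <- phi * (model$nu[i] + model$s[i] * z^2 * phi) + model$mu[i]
    disc <- B^2 - 4 * A * C
    root <- 2 * C / (-B + sqrt(disc))
    if (any(!is.finite(root)))
      stop(sprintf(
        "pgf evaluation failed in compartment %d (degenerate quadratic)", i))
    phi <- root
  }
  list(phi = phi, pd = pd, pb = pb)
}

#' Progeny-size distribution for the irreversible model
#'
#' Computes \eqn{P(G_i = k)} for a progenitor in compartment \code{start} of
#' an irreversible chain. The pgf is evaluated backwards from the terminal
#' closed form through the per-compartment quadratic functional equation, and
#' the power-series coefficients are extracted by trapezoidal (discrete
#' Fourier) contour inversion on a circle of radius \code{radius} inside the
#' unit disk.
#'
#' The contour radius trades round-off amplification (small \code{radius}
#' inflates \eqn{r^{-k}}) against aliasing from the series tail
#' (\code{radius} near 1); the default 0.9 with \code{4 * kmax} evaluation
#' points keeps both below about \code{1e-10} for well-behaved subcritical
#' chains. Coefficients more negative than \code{neg_tol} raise an error;
#' larger (round-off level) negative mass is clipped to zero.
#'
#' @param model an irreversible \code{compartment_model}.
#' @param start start compartment, in \code{1..N}.
#' @param kmax largest progeny size evaluated.
#' @param radius contour radius, in (0, 1).
#' @param npoints number of contour points (at least \code{kmax + 1}).
#' @param neg_tol tolerance for negative inverted mass.
#' @return A \code{pgf_series}. When the finiteness conditions fail (some
#'   \eqn{\Delta_i \le 0}) the distribution is defective: the tail mass then
#'   estimates \eqn{P(G_i = \infty)} as \eqn{1 - \Phi_i(1^-)} and a warning
#'   is issued.
#' @export
progeny_distribution_irreversible <- function(model, start, kmax = 200,
                                              radius = 0.9,
                                              npoints = 4L * (kmax + 1L),
                                              neg_tol = 1e-8) {
  .require_full_model(model, "progeny_distribution_irreversible")
  if (!is_irreversible(model))
    stop("the pgf route is derived for the irreversible model (all xi = 0)")
  N <- model$N
  stopifnot(start >= 1L, start <= N, kmax >= 0, radius > 0, radius < 1)
  npoints <- max(as.integer(npoints), as.integer(kmax) + 1L)
  theta <- 2 * pi * (0:(npoints - 1L)) / npoints
  z <- radius * exp(1i * theta)
  ev <- .pgf_eval(model, start, z)
  coefs <- stats::fft(ev$phi) / npoints
  k <- 0:kmax
  probs <- Re(coefs[k + 1L]) / radius^k
  if (any(probs < -neg_tol))
    stop(sprintf(
      "contour inversion produced negative mass %.3g at k = %d; increase npoints or move the radius",
      min(probs), k[which.min(probs)]))
  clipped <- probs < 0
  if (any(clipped)) probs[clipped] <- 0
  tail <- max(0, 1 - sum(probs))
  subcritical <- all(derived_rates(model)$Delta[!.inert_compartments(model)] > 0)
  if (!subcritical) {
    phi1 <- Re(.pgf_eval(model, start, 1 - 1e-9 + 0i)$phi)
    warning(sprintf(
      "supercritical chain: distribution is defective, P(G = infinity) ~ %.4g included in the tail mass",
      max(0, 1 - phi1)))
  }
  new_pgf_series(start, probs, tail, ev$pd, ev$pb)
}
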