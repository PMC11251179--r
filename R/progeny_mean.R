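# Progeny means of a single progenitor: first-step tridiagonal systems solved
# by forward elimination / backward substitution exactly as the recursions
# are written (Thomas algorithm), not by a generic dense solve.

.require_full_model <- function(model, what) {
  if (inherits(model, "reduced_model"))
    stop(what, " needs the raw per-event rates (lambda, a, s); a reduced ",
         "model carries only the composites (Delta, Lambda), from which ",
         "they are not identifiable")
  stopifnot(inherits(model, "compartment_model"))
}

# Compartments with zero total event rate are inert (e.g. an accumulating
# terminal compartment): cells there have no progeny and the first-step
# equation degenerates to 0 = 0, solved by m = 0.
.inert_compartments <- function(model) {
  if (inherits(model, "reduced_model")) {
    L <- c(model$Lambda, 0)
    model$Delta == 0 & model$xi == 0 & L == 0
  } else {
    with(model, lambda + s + a + nu + xi + mu) == 0
  }
}

# Forward elimination for the progeny system J m = b:
# gamma_1 = -Lambda_1/Delta_1, pivot_i = Delta_i + xi_i gamma_{i-1},
# gamma_i = -Lambda_i/pivot_i, rho_i = (b_i + xi_i rho_{i-1})/pivot_i.
# Returns gamma, rho; errors if a pivot is non-positive (infinite progeny).
.progeny_elimination <- function(Delta, Lambda, xi, b, inert = NULL) {
  N <- length(Delta)
  if (is.null(inert)) inert <- rep(FALSE, N)
  gamma <- numeric(N); rho <- numeric(N)
  gamma_prev <- 0; rho_prev <- 0
  for (i in seq_len(N)) {
    if (inert[i]) {
      rho[i] <- 0; gamma[i] <- 0
      gamma_prev <- 0; rho_prev <- 0
      next
    }
    piv <- Delta[i] + xi[i] * gamma_prev
    if (piv <= 0) {
      cond <- if (i == 1L) "Delta_1 > 0"
              else sprintf("Delta_%d + xi_%d * gamma_%d > 0", i, i, i - 1L)
      stop(sprintf(
        "infinite progeny: finiteness condition %s is violated (pivot = %g)",
        cond, piv))
    }
    rho[i] <- (b[i] + xi[i] * rho_prev) / piv
    gamma[i] <- if (i < N) -Lambda[i] / piv else 0
    gamma_prev <- gamma[i]; rho_prev <- rho[i]
  }
  list(gamma = gamma, rho = rho)
}

.back_substitute <- function(gamma, rho) {
  N <- length(rho)
  x <- numeric(N)
  x[N] <- rho[N]
  if (N > 1L) for (i in (N - 1L):1L) x[i] <- rho[i] - gamma[i] * x[i + 1L]
  x
}

#' Mean total progeny of a single progenitor
#'
#' \eqn{m_i = E[G_i]}, the mean number of descendants (daughters,
#' granddaughters, ...) of one cell starting in \eqn{C_i}, excluding the
#' progenitor itself. Every division consumes the mother and contributes both
#' daughters to the progeny, so the source terms are
#' \eqn{b_i = 2(\lambda_i + a_i + s_i)} (and \eqn{2\lambda_N} in the last
#' compartment). The first-step tridiagonal system is solved by the printed
#' forward-elimination/backward-substitution recursion; the means are finite
#' iff \eqn{\Delta_1 > 0} and every pivot \eqn{\Delta_i + \xi_i \gamma_{i-1}}
#' is positive (irreversible: \eqn{\Delta_i > 0} for all \eqn{i}).
#'
#' @param model a \code{compartment_model} (raw rates required).
#' @return Numeric vector \code{m} of length \code{N}.
#' @export
mean_total_progeny <- function(model) {
  .require_full_model(model, "mean_total_progeny")
  dr <- derived_rates(model)
  b <- with(model, 2 * (lambda + a + s))
  el <- .progeny_elimination(dr$Delta, dr$Lambda, model$xi, b,
                             inert = .inert_compartments(model))
  .back_substitute(el$gamma, el$rho)
}

#' Mean progeny split by birth compartment
#'
#' \eqn{m_i(j) = E[G_i(j)]}, the mean number of progeny cells of a progenitor
#' from \eqn{C_i} that are born into compartment \eqn{C_j}. The per-event
#' sources are \eqn{d_{(i,i)} = 2\lambda_i + a_i} (self-renewal puts both
#' daughters in \eqn{C_i}, asymmetric division one) and
#' \eqn{d_{(i,i+1)} = 2 s_i + a_i}. Rows sum to [mean_total_progeny()], and
#' in the irreversible model \eqn{m_i(j) = 0} for \eqn{j < i}.
#'
#' @param model a \code{compartment_model}.
#' @return An \code{N x N} matrix; rows index the start compartment,
#'   columns the birth compartment.
#' @export
mean_progeny_by_compartment <- function(model) {
  .require_full_model(model, "mean_progeny_by_compartment")
  N <- model$N
  dr <- derived_rates(model)
  m <- matrix(0, N, N,
              dimnames = list(start = paste0("C", 1:N),
                              born_in = paste0("C", 1:N)))
  inert <- .inert_compartments(model)
  if (is_irreversible(model)) {
    bad <- dr$Delta <= 0 & !inert
    if (any(bad))
      stop(sprintf(
        "infinite progeny: finiteness condition Delta_%d > 0 is violated",
        which(bad)[1L]))
    safe_div <- function(num, den) ifelse(num == 0, 0, num / den)
    d_own  <- with(model, 2 * lambda + a)   # d_{(j,j)}
    d_next <- with(model, 2 * s + a)        # d_{(j-1,j)} evaluated at j-1
    ratio <- safe_div(dr$Lambda, dr$Delta[-N])   # Lambda_p / Delta_p, p < N
    for (i in seq_len(N)) {
      m[i, i] <- safe_div(d_own[i], dr$Delta[i])
      if (i < N) for (j in (i + 1L):N) {
        pref <- if (j - 2L >= i) prod(ratio[i:(j - 2L)]) else 1
        inner <- d_next[j - 1L] +
          safe_div(d_own[j] * dr$Lambda[j - 1L], dr$Delta[j])
        m[i, j] <- pref * safe_div(inner, dr$Delta[j - 1L])
      }
    }
  } else {
    for (j in seq_len(N)) {
      d <- numeric(N)
      d[j] <- 2 * model$lambda[j] + model$a[j]
      if (j > 1L) d[j - 1L] <- 2 * model$s[j - 1L] + model$a[j - 1L]
      el <- .progeny_elimination(dr$Delta, dr$Lambda, model$xi, d,
                                 inert = inert)
      m[, j] <- .back_substitute(el$gamma, el$rho)
    }
  }
  m
}
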