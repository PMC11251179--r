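#' Generator matrix of the mean-field dynamics
#'
#' The mean numbers of cells per compartment obey the linear system
#' \eqn{dC/dt = A C} with a tridiagonal generator: diagonal \eqn{-\Delta_i},
#' subdiagonal \eqn{\Lambda_{i-1}} (forward flux into \eqn{C_i}) and
#' superdiagonal \eqn{\xi_{i+1}} (backward flux).
#'
#' @param model a \code{compartment_model} or \code{reduced_model}.
#' @return An \code{N x N} numeric matrix.
#' @export
build_generator <- function(model) {
  red <- as_reduced(model)
  N <- red$N
  A <- diag(-red$Delta, nrow = N)
  if (N > 1L) {
    A[cbind(2:N, 1:(N - 1))] <- red$Lambda
    A[cbind(1:(N - 1), 2:N)] <- red$xi[2:N]
  }
  A
}

#' Mean compartment trajectory via the matrix exponential
#'
#' Evaluates \eqn{C(t) = e^{A t} C_0} on a user-supplied time grid. Exact in
#' \eqn{t} (no time stepping); works for reversible, irreversible and reduced
#' models alike.
#'
#' @param model a \code{compartment_model} or \code{reduced_model}.
#' @param C0 nonnegative initial mean vector, length \code{N}.
#' @param times nonnegative time points.
#' @return A \code{mean_trajectory} object: list with \code{times},
#'   \code{values} (a \code{length(times) x N} matrix), \code{method},
#'   \code{C0} and \code{label}.
#' @export
solve_mean_matrix_exp <- function(model, C0, times) {
  red <- as_reduced(model)
  N <- red$N
  stopifnot(length(C0) == N, all(C0 >= 0), all(times >= 0))
  A <- build_generator(red)
  values <- t(vapply(times, function(t) {
    as.numeric(Matrix::expm(A * t) %*% C0)
  }, numeric(N)))
  if (any(!is.finite(values)))
    stop("non-finite mean values; check rates and time horizon")
  new_mean_trajectory(times, values, "matrix_exponential", C0, red$label)
}

new_mean_trajectory <- function(times, values, method, C0, label = "") {
  colnames(values) <- paste0("C", seq_len(ncol(values)))
  structure(list(times = times, values = values, method = method,
                 C0 = C0, label = label),
            class = "mean_trajectory")
}

#' Closed-form mean trajectory for the irreversible model
#'
#' For the irreversible model (all \eqn{\xi_i = 0}) started from a single
#' progenitor in \eqn{C_1}, the mean number of cells in each compartment has
#' closed forms: a sum of exponentials when the net loss rates
#' \eqn{\Delta_i} are pairwise distinct; a gamma-shaped
#' \eqn{\Lambda^{i-1} t^{i-1} e^{-\Delta t} / (i-1)!} profile when they are
#' all equal; and, when the terminal compartment is accumulating
#' (\eqn{\Delta_N = 0}) with the remaining \eqn{\Delta} equal, the
#' complementary form expressing \eqn{E[C_N]} through the upstream
#' compartments. Mixed multiplicity patterns fall back to the matrix
#' exponential (with a notice).
#'
#' @param model an irreversible \code{compartment_model} or
#'   \code{reduced_model}.
#' @param times nonnegative time points.
#' @return A \code{mean_trajectory}; the \code{method} field records which
#'   closed form was used.
#' @export
mean_irreversible_closed_form <- function(model, times) {
  red <- as_reduced(model)
  if (!is_irreversible(red))
    stop("closed forms require an irreversible model (all xi = 0)")
  stopifnot(all(times >= 0))
  N <- red$N
  Delta <- red$Delta
  Lambda <- red$Lambda
  C0 <- c(1, rep(0, N - 1L))
  regime <- .delta_regime(Delta)
  if (regime == "mixed") {
    message("mixed repeated/distinct Delta values: using the matrix exponential")
    return(solve_mean_matrix_exp(red, C0, times))
  }
  values <- matrix(0, length(times), N)
  if (regime == "distinct") {
    # E[C_i(t)] = (prod_{l<i} Lambda_l) sum_j exp(-Delta_j t) /
    #             prod_{m != j} (Delta_m - Delta_j)
    values[, 1] <- exp(-Delta[1] * times)
    if (N > 1L) for (i in 2:N) {
      pref <- prod(Lambda[seq_len(i - 1L)])
      acc <- numeric(length(times))
      for (j in seq_len(i)) {
        denom <- prod(Delta[setdiff(seq_len(i), j)] - Delta[j])
        acc <- acc + exp(-Delta[j] * times) / denom
      }
      values[, i] <- pref * acc
    }
    method <- "closed_form_distinct"
  } else if (regime == "equal") {
    for (i in seq_len(N)) {
      pref <- if (i > 1L) prod(Lambda[seq_len(i - 1L)]) else 1
      values[, i] <- pref * times^(i - 1L) / factorial(i - 1L) *
        exp(-Delta[i] * times)
    }
    method <- "closed_form_equal"
  } else { # terminal_zero_equal
    for (i in seq_len(N - 1L)) {
      pref <- if (i > 1L) prod(Lambda[seq_len(i - 1L)]) else 1
      values[, i] <- pref * times^(i - 1L) / factorial(i - 1L) *
        exp(-Delta[i] * times)
    }
    ratio <- Lambda / Delta[-N]
    limitN <- prod(ratio)
    accN <- rep(limitN, length(times))
    for (j in seq_len(N - 1L))
      accN <- accN - values[, j] * prod(ratio[j:(N - 1L)])
    values[, N] <- accN
    method <- "closed_form_equal"
  }
  new_mean_trajectory(times, values, method, C0, red$label)
}

#' Limiting accumulation in the terminal compartment
#'
#' For an irreversible chain whose terminal compartment is accumulating
#' (\eqn{\lambda_N = \mu_N = 0}, hence \eqn{\Delta_N = 0}) and whose
#' intermediate compartments die out (\eqn{\Delta_i > 0} for \eqn{i < N}),
#' the mean number of cells that ever reach \eqn{C_N} per progenitor in
#' \eqn{C_1} is \eqn{\prod_{i<N} \Lambda_i / \Delta_i}.
#'
#' @param model an irreversible \code{compartment_model} or
#'   \code{reduced_model} with accumulating terminal compartment.
#' @return The limiting mean, a scalar. Multiply by \eqn{C_1(0)} for
#'   ensemble initial conditions.
#' @export
terminal_limit <- function(model) {
  red <- as_reduced(model)
  if (!is_irreversible(red))
    stop("terminal_limit requires an irreversible model")
  N <- red$N
  if (N < 2L) stop("terminal_limit needs at least two compartments")
  if (abs(red$Delta[N]) > .delta_tol(red$Delta))
    stop("terminal compartment must be accumulating (Delta_N = 0)")
  if (any(red$Delta[-N] <= 0))
    stop("extinction condition Delta_i > 0 fails for intermediate compartments")
  prod(red$Lambda / red$Delta[-N])
}

#' Mean-field stability of the compartment chain
#'
#' The zero state is exponentially stable if and only if every eigenvalue of
#' the generator has negative real part. For the irreversible model the
#' eigenvalues are exactly \eqn{\{-\Delta_i\}}.
#'
#' @param model a \code{compartment_model} or \code{reduced_model}.
#' @param tol stability margin on the spectral abscissa.
#' @return List with \code{stable} (logical) and \code{spectral_abscissa}
#'   (max real part of the generator eigenvalues).
#' @export
assess_stability <- function(model, tol = 1e-12) {
  A <- build_generator(model)
  abscissa <- max(Re(eigen(A, only.values = TRUE)$values))
  list(stable = abscissa < -tol, spectral_abscissa = abscissa)
}

#' @export
print.mean_trajectory <- function(x, ...) {
  cat(sprintf("Mean trajectory (%d time points, %d compartments; %s)%s\n",
              length(x$times), ncol(x$values), x$method,
              if (nzchar(x$label)) paste0(": ", x$label) else ""))
  n <- min(6L, length(x$times))
  print(cbind(time = x$times[seq_len(n)],
              signif(x$values[seq_len(n), , drop = FALSE], 6)))
  if (length(x$times) > n) cat("...\n")
  invisible(x)
}

#' @export
as.data.frame.mean_trajectory <- function(x, ...) {
  data.frame(time = rep(x$times, ncol(x$values)),
             compartment = rep(seq_len(ncol(x$values)), each = length(x$times)),
             mean = as.vector(x$values))
}
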