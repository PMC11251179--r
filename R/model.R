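#' Define a compartment-chain cell model
#'
#' Constructs the full per-compartment rate specification of a linear chain of
#' cell compartments \eqn{C_1, \ldots, C_N}. Cells in compartment \eqn{C_i}
#' self-renew at rate \eqn{\lambda_i} (both daughters stay in \eqn{C_i}),
#' divide symmetrically at rate \eqn{s_i} (both daughters move to
#' \eqn{C_{i+1}}), divide asymmetrically at rate \eqn{a_i} (one daughter
#' stays, one moves forward), differentiate forwards at rate \eqn{\nu_i} or
#' backwards at rate \eqn{\xi_i}, and die at rate \eqn{\mu_i}. All rates are
#' per cell and per unit time.
#'
#' Cells in the last compartment cannot divide symmetrically or
#' asymmetrically, nor differentiate forwards, and cells in the first
#' compartment cannot differentiate backwards; the corresponding entries
#' (\code{s[N]}, \code{a[N]}, \code{nu[N]}, \code{xi[1]}) are forced to zero
#' (with a warning if a nonzero value was supplied).
#'
#' @param lambda numeric vector of self-renewal rates, length \code{N}.
#' @param s symmetric-division rates; scalar or length \code{N}.
#' @param a asymmetric-division rates; scalar or length \code{N}.
#' @param nu forward differentiation rates; scalar or length \code{N}.
#' @param xi backward differentiation rates; scalar or length \code{N}.
#'   All-zero \code{xi} gives the irreversible model.
#' @param mu death rates, length \code{N}.
#' @param label optional free-text model name.
#' @return An object of class \code{compartment_model}: a list with fields
#'   \code{N}, \code{lambda}, \code{s}, \code{a}, \code{nu}, \code{xi},
#'   \code{mu}, \code{label}.
#' @seealso [derived_rates()], [validate_model()], [reduced_model()]
#' @examples
#' m <- compartment_model(lambda = c(0.9, 0.9, 0.9, 0), s = 0, a = 0,
#'                        nu = c(0.5, 0.5, 0.5, 0), mu = c(1, 1, 1, 0),
#'                        label = "only self-renewal")
#' derived_rates(m)$Delta
#' @export
compartment_model <- function(lambda, s = 0, a = 0, nu = 0, xi = 0, mu,
                              label = "") {
  N <- length(mu)
  if (N < 1L) stop("at least one compartment is required")
  if (length(lambda) != N)
    stop("`lambda` and `mu` must have the same length")
  rec <- function(x, nm) {
    if (length(x) == 1L) x <- rep(x, N)
    if (length(x) != N)
      stop(sprintf("`%s` must be a scalar or have length %d", nm, N))
    x
  }
  s  <- rec(s,  "s");  a <- rec(a, "a")
  nu <- rec(nu, "nu"); xi <- rec(xi, "xi")
  rates <- list(lambda = lambda, s = s, a = a, nu = nu, xi = xi, mu = mu)
  for (nm in names(rates)) {
    x <- rates[[nm]]
    if (!is.numeric(x) || any(!is.finite(x)))
      stop(sprintf("rate `%s` must be finite and numeric", nm))
    if (any(x < 0))
      stop(sprintf("negative rate: %s[%d] = %g", nm, which(x < 0)[1L],
                   x[which(x < 0)[1L]]))
  }
  forced <- character(0)
  if (s[N] != 0)  forced <- c(forced, sprintf("s[%d]", N))
  if (a[N] != 0)  forced <- c(forced, sprintf("a[%d]", N))
  if (nu[N] != 0) forced <- c(forced, sprintf("nu[%d]", N))
  if (xi[1] != 0) forced <- c(forced, "xi[1]")
  if (length(forced))
    warning("forced to zero (chain boundary): ", paste(forced, collapse = ", "))
  s[N] <- 0; a[N] <- 0; nu[N] <- 0; xi[1] <- 0
  structure(list(N = N, lambda = lambda, s = s, a = a, nu = nu, xi = xi,
                 mu = mu, label = as.character(label)),
            class = "compartment_model")
}

#' Define a reduced compartment-chain model
#'
#' Some published parameterisations report only the composite rates
#' \eqn{\Delta_i} (net per-compartment loss) and \eqn{\Lambda_i} (mean forward
#' flux), from which the individual event rates are not identifiable. The
#' reduced model carries exactly those composites (plus backward rates
#' \eqn{\xi_i}, zero for the irreversible model): enough to build the mean
#' generator and study stability, but not progeny or lifeline statistics.
#'
#' @param Delta numeric vector of net loss rates \eqn{\Delta_i}, length
#'   \code{N}.
#' @param Lambda numeric vector of forward flux rates \eqn{\Lambda_i}, length
#'   \code{N - 1}.
#' @param xi backward differentiation rates; scalar or length \code{N}
#'   (\code{xi[1]} forced to zero).
#' @param label optional free-text model name.
#' @return An object of class \code{reduced_model}.
#' @export
reduced_model <- function(Delta, Lambda, xi = 0, label = "") {
  N <- length(Delta)
  if (length(Lambda) != N - 1L)
    stop("`Lambda` must have length one less than `Delta`")
  if (length(xi) == 1L) xi <- rep(xi, N)
  if (length(xi) != N) stop("`xi` must be a scalar or have length N")
  if (any(!is.finite(Delta)) || any(!is.finite(Lambda)) || any(!is.finite(xi)))
    stop("all rates must be finite")
  if (any(Lambda < 0))
    stop(sprintf("negative rate: Lambda[%d]", which(Lambda < 0)[1L]))
  if (any(xi < 0))
    stop(sprintf("negative rate: xi[%d]", which(xi < 0)[1L]))
  xi[1] <- 0
  structure(list(N = N, Delta = Delta, Lambda = Lambda, xi = xi,
                 label = as.character(label)),
            class = "reduced_model")
}

#' Composite rates of a compartment model
#'
#' Computes the composite symbols used throughout the analytic machinery:
#' the net loss rates \eqn{\Delta_i} (\eqn{\mu_i + \nu_i + s_i + \xi_i -
#' \lambda_i}, with the boundary entries \eqn{\xi_1 = 0} and \eqn{\nu_N = s_N
#' = 0} already enforced by the model), the forward flux rates
#' \eqn{\Lambda_i = \nu_i + a_i + 2 s_i}, the total event rates
#' \eqn{\Sigma_i = \mu_i + \nu_i + \lambda_i + a_i + s_i}, and the lifeline
#' variants \eqn{\bar\Delta_i = \mu_i + \nu_i + \xi_i} and
#' \eqn{\hat\Delta_i = \mu_i + \lambda_i + \xi_i + \nu_i}.
#'
#' @param model a \code{compartment_model}.
#' @return A list with components \code{Delta} (length \code{N}),
#'   \code{Lambda} (length \code{N - 1}), \code{Sigma}, \code{DeltaBar},
#'   \code{DeltaHat} (each length \code{N}).
#' @export
derived_rates <- function(model) {
  stopifnot(inherits(model, "compartment_model"))
  N <- model$N
  Delta <- with(model, mu + nu + s + xi - lambda)
  Lambda <- if (N > 1L)
    with(model, nu + a + 2 * s)[-N]
  else numeric(0)
  list(Delta = Delta,
       Lambda = Lambda,
       Sigma = with(model, mu + nu + lambda + a + s),
       DeltaBar = with(model, mu + nu + xi),
       DeltaHat = with(model, mu + lambda + xi + nu))
}

#' Collapse a full model to its reduced parameterisation
#'
#' @param model a \code{compartment_model}.
#' @return The corresponding \code{reduced_model} carrying
#'   \eqn{(\Delta, \Lambda, \xi)}.
#' @export
as_reduced <- function(model) {
  if (inherits(model, "reduced_model")) return(model)
  dr <- derived_rates(model)
  reduced_model(dr$Delta, dr$Lambda, xi = model$xi, label = model$label)
}

#' Is the model irreversible (no backward differentiation)?
#' @param model a \code{compartment_model} or \code{reduced_model}.
#' @return \code{TRUE} when all \eqn{\xi_i = 0}.
#' @export
is_irreversible <- function(model) all(model$xi == 0)

# Relative tolerance used to decide whether two Delta values coincide; the
# distinct-Delta closed forms divide by Delta_m - Delta_j.
.delta_tol <- function(Delta, rel = 1e-9) rel * max(abs(Delta), 1e-300)

# Classify the multiplicity pattern of Delta: "distinct", "equal",
# "terminal_zero_equal" (Delta_N = 0, the rest all equal), or "mixed".
.delta_regime <- function(Delta, tol = .delta_tol(Delta)) {
  N <- length(Delta)
  if (N == 1L) return("distinct")
  d <- sort(Delta)
  pairwise_distinct <- all(diff(d) > tol)
  if (pairwise_distinct) return("distinct")
  if (max(Delta) - min(Delta) <= tol) return("equal")
  head <- Delta[-N]
  if (abs(Delta[N]) <= tol && (max(head) - min(head)) <= tol)
    return("terminal_zero_equal")
  "mixed"
}

#' Validate a compartment model
#'
#' Runs the structural and dynamical diagnostics that decide which analytic
#' routes are available: irreversibility, mean-field stability (all generator
#' eigenvalues with negative real part), finiteness of the progeny
#' (\eqn{\Delta_1 > 0} and positive pivots \eqn{\Delta_i + \xi_i \gamma_{i-1}}
#' along the tridiagonal recursion; for the irreversible model simply
#' \eqn{\Delta_i > 0} for all \eqn{i}), and whether the \eqn{\Delta_i} are
#' pairwise distinct (so that the distinct-eigenvalue closed forms are safe).
#'
#' @param model a \code{compartment_model} or \code{reduced_model}.
#' @return A list of flags: \code{is_irreversible}, \code{mean_stable},
#'   \code{spectral_abscissa}, \code{progeny_finite}, \code{distinct_Delta},
#'   \code{delta_regime}.
#' @export
validate_model <- function(model) {
  red <- as_reduced(model)
  Delta <- red$Delta
  st <- assess_stability(model)
  # Progeny finiteness follows the pivots of the tridiagonal solve; inert
  # compartments (no events at all) host no progeny and are skipped.
  piv <- .thomas_pivots(Delta, red$Lambda, red$xi,
                        inert = .inert_compartments(model))
  regime <- .delta_regime(Delta)
  list(is_irreversible = is_irreversible(model),
       mean_stable = st$stable,
       spectral_abscissa = st$spectral_abscissa,
       progeny_finite = all(piv > 0),
       distinct_Delta = identical(regime, "distinct"),
       delta_regime = regime)
}

# Pivots Delta_i + xi_i * gamma_{i-1} of the forward elimination (gamma_0 = 0);
# inert compartments report a passing pivot of +Inf.
.thomas_pivots <- function(Delta, Lambda, xi, inert = rep(FALSE, length(Delta))) {
  N <- length(Delta)
  piv <- numeric(N)
  gamma_prev <- 0
  for (i in seq_len(N)) {
    if (inert[i]) {
      piv[i] <- Inf
      gamma_prev <- 0
      next
    }
    piv[i] <- Delta[i] + xi[i] * gamma_prev
    gamma_prev <- if (i < N && piv[i] != 0) -Lambda[i] / piv[i] else 0
  }
  piv
}

#' @export
print.compartment_model <- function(x, ...) {
  cat(sprintf("Compartment-chain model (%d compartments)%s\n", x$N,
              if (nzchar(x$label)) paste0(": ", x$label) else ""))
  tab <- rbind(lambda = x$lambda, s = x$s, a = x$a, nu = x$nu,
               xi = x$xi, mu = x$mu)
  colnames(tab) <- paste0("C", seq_len(x$N))
  print(signif(tab, 6))
  invisible(x)
}

#' @export
print.reduced_model <- function(x, ...) {
  cat(sprintf("Reduced compartment-chain model (%d compartments)%s\n", x$N,
              if (nzchar(x$label)) paste0(": ", x$label) else ""))
  cat("Delta: ", paste(signif(x$Delta, 6), collapse = ", "), "\n")
  cat("Lambda:", paste(signif(x$Lambda, 6), collapse = ", "), "\n")
  if (any(x$xi > 0))
    cat("xi:    ", paste(signif(x$xi, 6), collapse = ", "), "\n")
  invisible(x)
}
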