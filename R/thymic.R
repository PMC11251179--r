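# Bifurcated thymocyte-development topology:
#   pre-DP (1) -> post-DP (2) -> {CD4 SP (4), CD8 SP (8)} -> periphery.
# A tracked cell dies in one of the four compartments or is exported to the
# periphery through one of the two SP branches. Kept separate from the
# linear-chain machinery: the bifurcation admits simple closed forms
# (products of competing-risk ratios) for every statistic of interest.

.thymic_outcomes <- c("die_preDP", "die_postDP", "die_CD4SP", "die_CD8SP",
                      "exit_CD4", "exit_CD8")
.thymic_rates <- c("mu1", "nu1", "mu2", "nu24", "nu28", "lam4", "lam8",
                   "mu4", "mu8", "nu4", "nu8")

#' Thymocyte development model
#'
#' Rates (per day) of the bifurcated thymic topology: pre-DP cells die
#' (\code{mu1}) or mature to post-DP (\code{nu1}); post-DP cells die
#' (\code{mu2}) or are selected into the CD4 SP (\code{nu24}) or CD8 SP
#' (\code{nu28}) branch; SP cells divide by self-renewal (\code{lam4},
#' \code{lam8}), die (\code{mu4}, \code{mu8}) or are exported to the
#' periphery (\code{nu4}, \code{nu8}). Defaults are the published
#' parameterisation of the thymic case study.
#'
#' @param mu1,nu1,mu2,nu24,nu28,lam4,lam8,mu4,mu8,nu4,nu8 nonnegative rates
#'   (1/day).
#' @return An object of class \code{thymic_model}.
#' @export
thymic_model <- function(mu1 = 0.263, nu1 = 0.137, mu2 = 1.369,
                         nu24 = 0.07, nu28 = 0.054,
                         lam4 = 0.216, lam8 = 0.093,
                         mu4 = 0.04, mu8 = 0.11,
                         nu4 = 0.21, nu8 = 0.14) {
  rates <- list(mu1 = mu1, nu1 = nu1, mu2 = mu2, nu24 = nu24, nu28 = nu28,
                lam4 = lam4, lam8 = lam8, mu4 = mu4, mu8 = mu8,
                nu4 = nu4, nu8 = nu8)
  for (nm in names(rates)) {
    x <- rates[[nm]]
    if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < 0)
      stop(sprintf("rate `%s` must be a single finite nonnegative number", nm))
  }
  structure(rates, class = "thymic_model")
}

#' @export
print.thymic_model <- function(x, ...) {
  cat("Thymocyte development model (rates per day)\n")
  print(unlist(x[.thymic_rates]))
  invisible(x)
}

# Each fate probability is a product of competing-risk ratios
# rate / (sum of competing rates); the factor table below drives both the
# probabilities and their closed-form elasticities.
.thymic_factors <- function() {
  stage1 <- c("mu1", "nu1")
  stage2 <- c("mu2", "nu24", "nu28")
  stage4 <- c("mu4", "nu4")
  stage8 <- c("mu8", "nu8")
  list(
    die_preDP  = list(list(num = "mu1",  denom = stage1)),
    die_postDP = list(list(num = "nu1",  denom = stage1),
                      list(num = "mu2",  denom = stage2)),
    die_CD4SP  = list(list(num = "nu1",  denom = stage1),
                      list(num = "nu24", denom = stage2),
                      list(num = "mu4",  denom = stage4)),
    die_CD8SP  = list(list(num = "nu1",  denom = stage1),
                      list(num = "nu28", denom = stage2),
                      list(num = "mu8",  denom = stage8)),
    exit_CD4   = list(list(num = "nu1",  denom = stage1),
                      list(num = "nu24", denom = stage2),
                      list(num = "nu4",  denom = stage4)),
    exit_CD8   = list(list(num = "nu1",  denom = stage1),
                      list(num = "nu28", denom = stage2),
                      list(num = "nu8",  denom = stage8))
  )
}

.thymic_stage_sums <- function(model) {
  list(s1 = model$mu1 + model$nu1,
       s2 = model$mu2 + model$nu24 + model$nu28,
       s4 = model$mu4 + model$nu4,
       s8 = model$mu8 + model$nu8)
}

#' Fate statistics of a tracked pre-DP thymocyte
#'
#' Closed-form lifeline statistics for a single cell entering as pre-DP: the
#' probability of each of the six terminal outcomes (death in one of the
#' four compartments, or export to the periphery through the CD4 or CD8
#' branch), the mean number of divisions performed while visiting each SP
#' compartment, and the mean journey duration
#' \deqn{\tau_1 = \frac{1}{\mu_1+\nu_1}\left[
#'   \frac{\nu_1}{\mu_2+\nu_{24}+\nu_{28}}\left(
#'   \frac{\nu_{24}}{\mu_4+\nu_4} + \frac{\nu_{28}}{\mu_8+\nu_8} + 1\right)
#'   + 1 \right].}
#' The six outcome probabilities sum to one exactly.
#'
#' @param model a \code{thymic_model}.
#' @return A \code{thymic_fates} object: list with \code{beta} (named
#'   probability vector over the six outcomes), \code{eta4}, \code{eta8}
#'   (mean divisions in the CD4/CD8 SP compartments), \code{eta}
#'   (\code{eta4 + eta8}) and \code{tau1} (days).
#' @export
thymic_fates <- function(model) {
  stopifnot(inherits(model, "thymic_model"))
  ss <- .thymic_stage_sums(model)
  if (any(unlist(ss) <= 0))
    stop("every stage needs a positive total exit rate")
  value <- function(fac) prod(vapply(fac, function(f) {
    model[[f$num]] / sum(unlist(model[f$denom]))
  }, numeric(1)))
  beta <- vapply(.thymic_factors(), value, numeric(1))
  reach4 <- model$nu1 / ss$s1 * model$nu24 / ss$s2
  reach8 <- model$nu1 / ss$s1 * model$nu28 / ss$s2
  eta4 <- reach4 * model$lam4 / ss$s4
  eta8 <- reach8 * model$lam8 / ss$s8
  tau1 <- (1 / ss$s1) *
    ((model$nu1 / ss$s2) *
       (model$nu24 / ss$s4 + model$nu28 / ss$s8 + 1) + 1)
  structure(list(beta = beta, eta4 = eta4, eta8 = eta8,
                 eta = eta4 + eta8, tau1 = tau1),
            class = "thymic_fates")
}

#' @export
print.thymic_fates <- function(x, ...) {
  cat("Fate of a tracked pre-DP thymocyte\n")
  print(round(x$beta, 4))
  cat(sprintf("mean divisions: CD4 SP %.4f + CD8 SP %.4f = %.4f\n",
              x$eta4, x$eta8, x$eta))
  cat(sprintf("mean journey duration: %.2f days\n", x$tau1))
  invisible(x)
}

#' Closed-form elasticity table of the thymic fate probabilities
#'
#' Each fate probability is a product of competing-risk ratios
#' \eqn{\theta_{num} / \sum \theta_{denom}}, so its elasticity with respect
#' to a rate \eqn{\theta} is the sum over factors of
#' \eqn{1_{\theta = num} - \theta / \sum \theta_{denom} \cdot
#' 1_{\theta \in denom}}. Rates absent from a probability's factors (the SP
#' division rates, for every fate probability) have elasticity exactly zero.
#'
#' @param model a \code{thymic_model}.
#' @return A \code{6 x 11} matrix: rows are the outcomes, columns the rates.
#' @export
thymic_elasticity_table <- function(model) {
  stopifnot(inherits(model, "thymic_model"))
  factors <- .thymic_factors()
  out <- matrix(0, length(.thymic_outcomes), length(.thymic_rates),
                dimnames = list(.thymic_outcomes, .thymic_rates))
  for (o in .thymic_outcomes) for (r in .thymic_rates) {
    e <- 0
    for (f in factors[[o]]) {
      if (r == f$num) e <- e + 1
      if (r %in% f$denom) e <- e - model[[r]] / sum(unlist(model[f$denom]))
    }
    out[o, r] <- e
  }
  out
}

#' Simulate the lifeline of single pre-DP thymocytes
#'
#' Monte-Carlo counterpart of [thymic_fates()]: simulates the embedded jump
#' chain of the tracked cell through the bifurcated topology. Stage sojourns
#' are exponential in the stage's total exit rate; in an SP compartment the
#' number of self-renewal divisions before death/export is geometric and the
#' sojourn is the corresponding Erlang sum.
#'
#' @param model a \code{thymic_model}.
#' @param n number of replicate cells.
#' @param seed integer RNG seed.
#' @return A data frame with one row per cell: \code{outcome} (factor over
#'   the six fates), \code{time} (days), \code{d4}, \code{d8} (divisions in
#'   each SP compartment).
#' @export
simulate_thymocyte <- function(model, n = 1L, seed = NULL) {
  stopifnot(inherits(model, "thymic_model"), n >= 1L)
  if (!is.null(seed)) set.seed(seed)
  ss <- .thymic_stage_sums(model)
  outcome <- character(n)
  time <- stats::rexp(n, ss$s1)
  d4 <- integer(n); d8 <- integer(n)
  u1 <- stats::runif(n)
  died1 <- u1 < model$mu1 / ss$s1
  outcome[died1] <- "die_preDP"
  alive <- which(!died1)
  if (length(alive)) {
    time[alive] <- time[alive] + stats::rexp(length(alive), ss$s2)
    u2 <- stats::runif(length(alive))
    p_die2 <- model$mu2 / ss$s2
    p_to4 <- model$nu24 / ss$s2
    died2 <- u2 < p_die2
    to4 <- !died2 & u2 < p_die2 + p_to4
    to8 <- !died2 & !to4
    outcome[alive[died2]] <- "die_postDP"
    sp <- function(idx, lam, mu, nu, branch) {
      if (!length(idx)) return(list(idx = idx, d = integer(0)))
      tot <- lam + mu + nu
      d <- stats::rgeom(length(idx), prob = (mu + nu) / tot)
      time[idx] <<- time[idx] + stats::rgamma(length(idx), shape = d + 1,
                                              rate = tot)
      exported <- stats::runif(length(idx)) < nu / (mu + nu)
      outcome[idx] <<- ifelse(exported, paste0("exit_", branch),
                              paste0("die_", branch, "SP"))
      list(idx = idx, d = d)
    }
    r4 <- sp(alive[to4], model$lam4, model$mu4, model$nu4, "CD4")
    r8 <- sp(alive[to8], model$lam8, model$mu8, model$nu8, "CD8")
    d4[r4$idx] <- r4$d
    d8[r8$idx] <- r8$d
  }
  data.frame(outcome = factor(outcome, levels = .thymic_outcomes),
             time = time, d4 = d4, d8 = d8)
}
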