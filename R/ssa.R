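# Exact stochastic simulation of the compartment-chain processes: the
# population CTMC (Gillespie direct method), single-cell lifelines, and
# progeny trees of a single progenitor.

.event_types <- c("self_renewal", "symmetric", "asymmetric",
                  "forward", "backward", "death")

# Deterministic per-replicate seed derived from (master seed, replicate
# index), so replicate sets are reproducible and order-independent.
.replicate_seed <- function(seed, r) {
  ((as.numeric(seed) %% 65536) * 32749 + 7919 * r) %% 2147483647
}

#' Simulate the compartment population process
#'
#' Exact (Gillespie direct method) simulation of the population CTMC: each
#' event picks a compartment with probability proportional to its total
#' event rate \eqn{n_i (\lambda_i + s_i + a_i + \nu_i + \xi_i + \mu_i)},
#' then an event type, and updates the integer state accordingly
#' (self-renewal \eqn{+1}; symmetric division \eqn{-1} here, \eqn{+2} next;
#' asymmetric \eqn{+1} next; differentiation moves one cell; death
#' \eqn{-1}). States are recorded on the save grid only.
#'
#' @param model a \code{compartment_model}.
#' @param C0 nonnegative integer initial counts, length \code{N}.
#' @param t_max simulation horizon.
#' @param save_times times at which the state is recorded (defaults to 51
#'   equispaced points in \code{[0, t_max]}).
#' @param seed integer RNG seed.
#' @param max_events safety cap; exceeding it truncates the trajectory and
#'   sets the \code{truncated} flag (relevant for supercritical models).
#' @param log_events keep the full event log (time, compartment, type)?
#' @return A \code{population_trajectory}: list with \code{save_times},
#'   \code{states} (matrix, one row per save time), \code{event_counts}
#'   (named by event type), \code{truncated}, \code{seed} and (optionally)
#'   \code{events}.
#' @export
simulate_population <- function(model, C0, t_max, save_times = NULL,
                                seed = NULL, max_events = 1e7,
                                log_events = FALSE) {
  .require_full_model(model, "simulate_population")
  N <- model$N
  stopifnot(length(C0) == N, all(C0 >= 0), all(C0 == round(C0)), t_max > 0)
  if (is.null(save_times)) save_times <- seq(0, t_max, length.out = 51L)
  stopifnot(all(save_times >= 0), all(save_times <= t_max))
  save_times <- sort(save_times)
  if (!is.null(seed)) set.seed(seed)
  ratemat <- with(model, rbind(lambda, s, a, nu, xi, mu))  # 6 x N per-cell
  percell <- colSums(ratemat)
  n <- as.integer(C0)
  t <- 0
  states <- matrix(0L, length(save_times), N,
                   dimnames = list(NULL, paste0("C", 1:N)))
  isave <- 1L
  counts <- stats::setNames(numeric(6), .event_types)
  events <- if (log_events) vector("list", 1024L) else NULL
  nev <- 0L
  truncated <- FALSE
  repeat {
    tot <- n * percell
    T_all <- sum(tot)
    t_next <- if (T_all > 0) t + stats::rexp(1L, T_all) else Inf
    while (isave <= length(save_times) && save_times[isave] < t_next) {
      states[isave, ] <- n
      isave <- isave + 1L
    }
    if (!is.finite(t_next) || t_next > t_max) break
    t <- t_next
    i <- if (N == 1L) 1L else sample.int(N, 1L, prob = tot)
    ev <- sample.int(6L, 1L, prob = ratemat[, i])
    if (ev == 1L) {                       # self-renewal
      n[i] <- n[i] + 1L
    } else if (ev == 2L) {                # symmetric division
      n[i] <- n[i] - 1L; n[i + 1L] <- n[i + 1L] + 2L
    } else if (ev == 3L) {                # asymmetric division
      n[i + 1L] <- n[i + 1L] + 1L
    } else if (ev == 4L) {                # forward differentiation
      n[i] <- n[i] - 1L; n[i + 1L] <- n[i + 1L] + 1L
    } else if (ev == 5L) {                # backward differentiation
      n[i] <- n[i] - 1L; n[i - 1L] <- n[i - 1L] + 1L
    } else {                              # death
      n[i] <- n[i] - 1L
    }
    counts[ev] <- counts[ev] + 1
    nev <- nev + 1L
    if (log_events) {
      if (nev > length(events)) events <- c(events, vector("list", length(events)))
      events[[nev]] <- list(time = t, compartment = i, type = .event_types[ev])
    }
    if (nev >= max_events) { truncated <- TRUE; break }
  }
  while (isave <= length(save_times)) {   # state is frozen past the last event
    states[isave, ] <- n
    isave <- isave + 1L
  }
  structure(list(save_times = save_times, states = states,
                 event_counts = counts, truncated = truncated, seed = seed,
                 events = if (log_events) events[seq_len(nev)] else NULL),
            class = "population_trajectory")
}

#' Ensemble of population trajectories
#'
#' Runs [simulate_population()] over independent replicates with
#' per-replicate seeds derived from the master seed, and returns the saved
#' states as an array.
#'
#' @inheritParams simulate_population
#' @param replicates number of replicates.
#' @return List with \code{save_times}, \code{states} (array
#'   \code{replicates x times x N}), \code{truncated} (logical per
#'   replicate).
#' @export
simulate_population_ensemble <- function(model, C0, t_max, save_times = NULL,
                                         replicates = 100L, seed = 1L,
                                         max_events = 1e7) {
  if (is.null(save_times)) save_times <- seq(0, t_max, length.out = 51L)
  states <- array(0, dim = c(replicates, length(save_times), model$N))
  truncated <- logical(replicates)
  for (r in seq_len(replicates)) {
    tr <- simulate_population(model, C0, t_max, save_times,
                              seed = .replicate_seed(seed, r),
                              max_events = max_events)
    states[r, , ] <- tr$states
    truncated[r] <- tr$truncated
  }
  list(save_times = save_times, states = states, truncated = truncated)
}

#' Simulate a single-cell lifeline
#'
#' Simulates the tracked-cell chain of the lifeline analysis: the cell sits
#' in one compartment at a time, divides by self-renewal (staying put),
#' moves forwards or backwards, or dies. Requires \code{s = a = 0}.
#'
#' @param model a \code{compartment_model} with \code{s = a = 0}.
#' @param start start compartment.
#' @param seed integer RNG seed.
#' @return A \code{lifeline_record}: list with \code{T} (lifetime),
#'   \code{D} (total divisions), \code{D_by_compartment},
#'   \code{death_compartment}, and \code{history} (data frame of visited
#'   compartments and sojourn times).
#' @export
simulate_lifeline <- function(model, start = 1L, seed = NULL) {
  .require_lifeline_model(model)
  if (!is.null(seed)) set.seed(seed)
  N <- model$N
  stopifnot(start >= 1L, start <= N)
  i <- as.integer(start)
  t <- 0
  D <- integer(N)
  comp_hist <- integer(0); sojourn_hist <- numeric(0)
  entered <- 0
  repeat {
    rates <- c(model$lambda[i], model$nu[i], model$xi[i], model$mu[i])
    tot <- sum(rates)
    if (tot <= 0) stop("tracked cell reached a compartment with no exit events")
    t <- t + stats::rexp(1L, tot)
    ev <- sample.int(4L, 1L, prob = rates)
    if (ev == 1L) {                      # division: line continues in C_i
      D[i] <- D[i] + 1L
    } else {
      comp_hist <- c(comp_hist, i)
      sojourn_hist <- c(sojourn_hist, t - entered)
      entered <- t
      if (ev == 2L) i <- i + 1L
      else if (ev == 3L) i <- i - 1L
      else break                         # death
    }
  }
  structure(list(T = t, D = sum(D), D_by_compartment = D,
                 death_compartment = comp_hist[length(comp_hist)],
                 history = data.frame(compartment = comp_hist,
                                      sojourn = sojourn_hist),
                 seed = seed),
            class = "lifeline_record")
}

#' Simulate many lifelines (vectorised)
#'
#' Replicate-level counterpart of [simulate_lifeline()]: all active
#' replicates advance one embedded-chain event per sweep, which keeps the
#' cost per lifeline small even for tens of thousands of replicates.
#'
#' @inheritParams simulate_lifeline
#' @param replicates number of lifelines.
#' @return A data frame with one row per lifeline: \code{T}, \code{D},
#'   \code{D1..DN} (divisions per compartment) and
#'   \code{death_compartment}.
#' @export
simulate_lifelines <- function(model, start = 1L, replicates = 1000L,
                               seed = NULL) {
  .require_lifeline_model(model)
  if (!is.null(seed)) set.seed(seed)
  N <- model$N
  stopifnot(start >= 1L, start <= N)
  comp <- rep(as.integer(start), replicates)
  T_acc <- numeric(replicates)
  D <- matrix(0L, replicates, N)
  death <- integer(replicates)
  active <- seq_len(replicates)
  tot_by_comp <- with(model, lambda + nu + xi + mu)
  # cumulative event probabilities per compartment: division, forward, back
  p_div <- model$lambda / tot_by_comp
  p_fwd <- p_div + model$nu / tot_by_comp
  p_bwd <- p_fwd + model$xi / tot_by_comp
  while (length(active)) {
    ci <- comp[active]
    T_acc[active] <- T_acc[active] + stats::rexp(length(active),
                                                 tot_by_comp[ci])
    u <- stats::runif(length(active))
    div <- u < p_div[ci]
    fwd <- !div & u < p_fwd[ci]
    bwd <- !div & !fwd & u < p_bwd[ci]
    die <- !div & !fwd & !bwd
    D[cbind(active[div], ci[div])] <- D[cbind(active[div], ci[div])] + 1L
    comp[active[fwd]] <- ci[fwd] + 1L
    comp[active[bwd]] <- ci[bwd] - 1L
    death[active[die]] <- ci[die]
    active <- active[!die]
  }
  out <- data.frame(T = T_acc, D = rowSums(D), death_compartment = death)
  colnames(D) <- paste0("D", seq_len(N))
  cbind(out, as.data.frame(D))
}

# Core progeny-tree simulation (does not touch the RNG seed).
.progeny_core <- function(model, start, max_progeny, max_events) {
  N <- model$N
  n <- integer(N); n[start] <- 1L
  G <- integer(N)
  ratemat <- with(model, rbind(lambda, s, a, nu, xi, mu))
  percell <- colSums(ratemat)
  nev <- 0L
  capped <- FALSE
  repeat {
    tot <- n * percell
    if (sum(tot) <= 0) break
    i <- if (N == 1L) 1L else sample.int(N, 1L, prob = tot)
    ev <- sample.int(6L, 1L, prob = ratemat[, i])
    if (ev == 1L) {        # self-renewal: mother consumed, two daughters here
      n[i] <- n[i] + 1L; G[i] <- G[i] + 2L
    } else if (ev == 2L) { # symmetric: two daughters in the next compartment
      n[i] <- n[i] - 1L; n[i + 1L] <- n[i + 1L] + 2L; G[i + 1L] <- G[i + 1L] + 2L
    } else if (ev == 3L) { # asymmetric: one daughter here, one forward
      n[i + 1L] <- n[i + 1L] + 1L
      G[i] <- G[i] + 1L; G[i + 1L] <- G[i + 1L] + 1L
    } else if (ev == 4L) {
      n[i] <- n[i] - 1L; n[i + 1L] <- n[i + 1L] + 1L
    } else if (ev == 5L) {
      n[i] <- n[i] - 1L; n[i - 1L] <- n[i - 1L] + 1L
    } else {
      n[i] <- n[i] - 1L
    }
    nev <- nev + 1L
    if (sum(G) >= max_progeny || nev >= max_events) { capped <- TRUE; break }
  }
  list(G = sum(G), G_by_compartment = G, capped = capped)
}

#' Simulate the progeny tree of a single progenitor
#'
#' Event-driven simulation of the branching process started from one cell in
#' compartment \code{start}, run until the lineage is extinct (or a cap is
#' hit). Every division consumes the mother and adds both daughters to the
#' progeny count of the compartment in which they are born; the progenitor
#' itself is not counted. The progeny of the trajectory is exactly
#' \eqn{G = \sum_j G(j)}, attributing two cells to \eqn{C_i} per
#' self-renewal, one each to \eqn{C_i} and \eqn{C_{i+1}} per asymmetric
#' division, and two to \eqn{C_{i+1}} per symmetric division.
#'
#' @param model a \code{compartment_model}.
#' @param start start compartment.
#' @param seed integer RNG seed.
#' @param max_progeny,max_events safety caps turning runaway (supercritical)
#'   growth into flagged records.
#' @return A \code{progeny_record}: list with \code{G},
#'   \code{G_by_compartment} and \code{capped}.
#' @export
simulate_progeny <- function(model, start = 1L, seed = NULL,
                             max_progeny = 1e6, max_events = 1e7) {
  .require_full_model(model, "simulate_progeny")
  stopifnot(start >= 1L, start <= model$N)
  if (!is.null(seed)) set.seed(seed)
  structure(c(.progeny_core(model, as.integer(start), max_progeny,
                            max_events),
              list(seed = seed)),
            class = "progeny_record")
}

#' Simulate many progeny trees
#'
#' @inheritParams simulate_progeny
#' @param replicates number of progenitors.
#' @return A data frame with one row per progenitor: \code{G},
#'   \code{G1..GN} and \code{capped}.
#' @export
simulate_progenies <- function(model, start = 1L, replicates = 1000L,
                               seed = 1L, max_progeny = 1e6,
                               max_events = 1e7) {
  .require_full_model(model, "simulate_progenies")
  N <- model$N
  G <- matrix(0L, replicates, N)
  capped <- logical(replicates)
  for (r in seq_len(replicates)) {
    set.seed(.replicate_seed(seed, r))
    rec <- .progeny_core(model, as.integer(start), max_progeny, max_events)
    G[r, ] <- rec$G_by_compartment
    capped[r] <- rec$capped
  }
  out <- data.frame(G = rowSums(G), capped = capped)
  colnames(G) <- paste0("G", seq_len(N))
  cbind(out, as.data.frame(G))
}

#' Summary statistics of an ensemble of replicate records
#'
#' @param records a data frame (or numeric matrix) of per-replicate numeric
#'   statistics, one row per replicate.
#' @return A data frame with one row per statistic: \code{mean}, \code{var}
#'   (unbiased), \code{se} (\eqn{sd/\sqrt{R}}) and \code{n}.
#' @export
ensemble_summary <- function(records) {
  x <- as.data.frame(records)
  num <- vapply(x, is.numeric, logical(1))
  x <- x[num]
  if (nrow(x) < 2L) stop("at least two replicate records are required")
  data.frame(statistic = names(x),
             mean = vapply(x, mean, numeric(1)),
             var = vapply(x, stats::var, numeric(1)),
             se = vapply(x, function(v) stats::sd(v) / sqrt(length(v)),
                         numeric(1)),
             n = nrow(x), row.names = NULL)
}
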