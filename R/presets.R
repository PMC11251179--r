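#' Built-in case-study parameterisations
#'
#' Returns one of the published parameter sets used throughout the package's
#' worked examples.
#'
#' \describe{
#'   \item{\code{four_comp_*}}{A four-compartment chain in which the terminal
#'     compartment is inert (no death, division or differentiation), so cells
#'     reaching it accumulate. Compartments 1--3 share death rate
#'     \eqn{\mu = 1}, forward differentiation \eqn{\nu = 1/2} and total
#'     division rate \eqn{\omega = 0.9}, split between self-renewal,
#'     symmetric and asymmetric division according to the scenario:
#'     \code{only_SR} (1, 0, 0), \code{dom_SR} (0.8, 0.1, 0.1),
#'     \code{dom_SD} (0.1, 0.8, 0.1), \code{dom_AD} (0.1, 0.1, 0.8).}
#'   \item{\code{hsc_table1}}{The five-compartment hematopoietic chain
#'     HSC1 -> HSC2 -> MPP1+2 -> MPP3 -> HPC1, available only in reduced
#'     \eqn{(\Delta, \Lambda)} form because the source reports composites
#'     only (units: per day). \eqn{\Delta_1 < 0}, so the HSC1 population
#'     grows without bound.}
#'   \item{\code{hsc_symm1}, \code{hsc_symmall}, \code{hsc_asymmall}}{The same
#'     chain with additional symmetric/asymmetric division rates layered on
#'     top: \eqn{\Delta_i \to \Delta_i + s_i},
#'     \eqn{\Lambda_i \to \Lambda_i + 2 s_i + a_i} (a direct consequence of
#'     the composite-rate definitions). \code{hsc_symm1} adds \code{s1} in
#'     the first compartment only; \code{hsc_symmall} adds \code{s} in
#'     compartments 1--4; \code{hsc_asymmall} adds \code{a} in compartments
#'     1--4 together with \eqn{s_1 = 5 \times 10^{-3}} per day so that
#'     extinction is guaranteed.}
#'   \item{\code{thymic_table2}}{The bifurcated thymocyte-development model;
#'     see [thymic_model()].}
#' }
#'
#' @param name preset name; one of \code{"four_comp_only_SR"},
#'   \code{"four_comp_dom_SR"}, \code{"four_comp_dom_SD"},
#'   \code{"four_comp_dom_AD"}, \code{"hsc_table1"}, \code{"hsc_symm1"},
#'   \code{"hsc_symmall"}, \code{"hsc_asymmall"}, \code{"thymic_table2"}.
#' @param s1,s,a scenario knobs for the HSC variants (per day). The published
#'   study explores \code{s1}/\code{s} in \{1e-2, 1e-1\} and \code{a} in
#'   \{1e-4, 1e-3, 1e-2, 1e-1\}; values outside those sets are accepted with
#'   a warning.
#' @return A \code{compartment_model}, \code{reduced_model} or
#'   \code{thymic_model}, depending on the preset.
#' @examples
#' load_case_study("four_comp_only_SR")
#' load_case_study("hsc_table1")
#' @export
load_case_study <- function(name, s1 = 1e-2, s = 1e-2, a = 1e-3) {
  four_comp <- function(p_sr, p_sd, p_ad, label) {
    omega <- 0.9
    compartment_model(
      lambda = c(rep(p_sr * omega, 3), 0),
      s      = c(rep(p_sd * omega, 3), 0),
      a      = c(rep(p_ad * omega, 3), 0),
      nu     = c(rep(0.5, 3), 0),
      xi     = 0,
      mu     = c(rep(1, 3), 0),
      label  = label)
  }
  hsc_Delta <- c(-0.0046197, 0.0017357, 0.0044844, 0.01556, 0.0293)
  hsc_Lambda <- c(0.016497, 0.007847, 0.032834, 0.16113)
  check_knob <- function(value, allowed, nm) {
    if (!any(abs(value - allowed) <= 1e-12 * pmax(allowed, 1)))
      warning(sprintf("%s = %g is outside the published scenario set {%s}",
                      nm, value, paste(allowed, collapse = ", ")))
  }
  switch(name,
    four_comp_only_SR = four_comp(1.0, 0.0, 0.0, "four compartments, only SR"),
    four_comp_dom_SR  = four_comp(0.8, 0.1, 0.1, "four compartments, dominant SR"),
    four_comp_dom_SD  = four_comp(0.1, 0.8, 0.1, "four compartments, dominant SD"),
    four_comp_dom_AD  = four_comp(0.1, 0.1, 0.8, "four compartments, dominant AD"),
    hsc_table1 = reduced_model(hsc_Delta, hsc_Lambda,
                               label = "HSC chain, only SR (per day)"),
    hsc_symm1 = {
      check_knob(s1, c(1e-2, 1e-1), "s1")
      D <- hsc_Delta; L <- hsc_Lambda
      D[1] <- D[1] + s1; L[1] <- L[1] + 2 * s1
      reduced_model(D, L, label = sprintf("HSC chain, Symm1 (s1 = %g)", s1))
    },
    hsc_symmall = {
      check_knob(s, c(1e-2, 1e-1), "s")
      D <- hsc_Delta; L <- hsc_Lambda
      D[1:4] <- D[1:4] + s; L <- L + 2 * s
      reduced_model(D, L, label = sprintf("HSC chain, SymmAll (s = %g)", s))
    },
    hsc_asymmall = {
      check_knob(a, c(1e-4, 1e-3, 1e-2, 1e-1), "a")
      s1_fixed <- 5e-3
      D <- hsc_Delta; L <- hsc_Lambda
      D[1] <- D[1] + s1_fixed
      L[1] <- L[1] + 2 * s1_fixed
      L <- L + a
      reduced_model(D, L,
                    label = sprintf("HSC chain, AsymmAll (a = %g, s1 = %g)",
                                    a, s1_fixed))
    },
    thymic_table2 = thymic_model(),
    stop(sprintf("unknown case study '%s'", name))
  )
}
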