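#' Ohmic membrane current
#'
#' `I = gbar * w * (V - Erev)`, with `w` the product of gate state variables.
#' Positive current is outward.
#'
#' @param gbar maximal conductance, uS (>= 0)
#' @param w open fraction in \[0, 1\]
#' @param v membrane potential, mV
#' @param erev reversal potential, mV
#' @return current in nA
#' @export
ohmicCurrent <- function(gbar, w, v, erev) {
  if (any(gbar < 0)) stop("maximal conductance must be >= 0")
  if (any(w < 0 | w > 1)) stop("gate value must lie in [0, 1]")
  gbar * w * (v - erev)
}

#' Goldman-Hodgkin-Katz calcium current
#'
#' `I = pbar * m^p * h^q * NA*qe*z * (cai*(-xi)/(exp(-xi)-1) - cao*xi/(exp(xi)-1))`
#' with `xi = z*qe*V/(k*T)`. `NA*qe` is the Faraday constant; `pbar` carries
#' the remaining dimensional factors so the result is in nA. Below
#' `|xi| < 1e-4` a second-order series keeps the expression numerically
#' stable (both Boltzmann factors tend to 1 as V -> 0, so the bracket tends
#' to `cai - cao`).
#'
#' @param pbar maximal permeability, scaled so output is nA (>= 0)
#' @param m,h activation/inactivation gate values in \[0, 1\]
#' @param cai,cao intracellular / extracellular calcium, mM (> 0)
#' @param v membrane potential, mV
#' @param p,q gate exponents
#' @param temperature Kelvin
#' @param z ion valence
#' @return current in nA (inward negative)
#' @export
ghkCurrent <- function(pbar, m, h, cai, cao, v, p = 3L, q = 1L,
                       temperature = 283.15, z = 2) {
  if (pbar < 0) stop("maximal permeability must be >= 0")
  if (any(c(m, h) < 0) || any(c(m, h) > 1)) stop("gate values must lie in [0, 1]")
  if (any(cai <= 0) || cao <= 0) stop("calcium concentrations must be positive")
  if (temperature <= 0) stop("temperature must be positive")
  w <- m^p * h^q
  vapply(seq_along(v), function(i) {
    cppGhkCurrent(pbar, w[min(i, length(w))], cai[min(i, length(cai))], cao,
                  v[i], temperature, z)
  }, numeric(1))
}

#' Intracellular calcium pool
#'
#' First-order buffering/extrusion model
#' `dCa/dt = (ca_rest - Ca)/tau_ca - f * I_Ca`, advanced by its exact
#' exponential solution over a step. Inward calcium current (negative nA)
#' raises the concentration.
#'
#' @param ca_rest resting concentration, mM
#' @param tau_ca removal time constant, ms
#' @param f current-to-concentration factor, mM per nA*ms
#' @return a `calcium_pool` list
#' @export
calciumPool <- function(ca_rest = 5e-5, tau_ca = 275.808, f = 1.0611e-5) {
  if (tau_ca <= 0) stop("tau_ca must be positive")
  if (ca_rest <= 0) stop("ca_rest must be positive")
  structure(list(ca_rest = ca_rest, tau_ca = tau_ca, f = f),
            class = "calcium_pool")
}

#' @rdname calciumPool
#' @param pool a `calcium_pool`
#' @param cai current concentration, mM
#' @param i_ca calcium current, nA
#' @param dt step, ms (> 0)
#' @return updated concentration, mM (always positive)
#' @export
stepCalcium <- function(pool, cai, i_ca, dt) {
  stopifnot(inherits(pool, "calcium_pool"), dt > 0)
  cppStepCalcium(cai, i_ca, dt, pool$ca_rest, pool$tau_ca, pool$f)
}
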