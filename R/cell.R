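# Column layouts shared with src/engine.cpp (1-based here, 0-based there).
CH <- list(COMP = 1L, KIND = 2L, G = 3L, EREV = 4L, P = 5L, Q = 6L,
           AVH = 7L, AK = 8L, ATT = 9L, AC0 = 10L, AAMP = 11L, AVHT = 12L,
           AK1 = 13L, AK2 = 14L, IVH = 15L, IK = 16L, ITT = 17L, IC0 = 18L,
           IAMP = 19L, IVHT = 20L, IK1 = 21L, IK2 = 22L, CADEP = 23L,
           KD = 24L, CAO = 25L, TEMP = 26L, Z = 27L, NCOL = 27L)
SY <- list(DRIVE = 1L, COMP = 2L, G = 3L, EREV = 4L, VTH = 5L, VSC = 6L,
           TAU = 7L, NCOL = 7L)
CAM <- list(COMP = 1L, REST = 2L, TAU = 3L, F = 4L, NCOL = 4L)

COMPARTMENTS <- c("axon", "soma", "secondary", "tertiary")

#' The 14 conductance names of an LP model
#'
#' Four axonal conductances (leak, Kd, A, Na), seven soma/neurite densities
#' shared across the soma-primary, secondary and tertiary compartments
#' (leak, MI, Kd, A, KCa, Ca permeability, h) and three synaptic conductances
#' (AB, PD, PY). Units: uS, except `p_Ca` (scaled permeability).
#'
#' @return character vector of length 14, fixed order
#' @export
conductanceNames <- function() {
  c("g_leak_axon", "g_Kd_axon", "g_A_axon", "g_Na_axon",
    "g_leak", "g_MI", "g_Kd", "g_A", "g_KCa", "p_Ca", "g_h",
    "g_synAB", "g_synPD", "g_synPY")
}

#' Construct and validate a conductance set
#'
#' @param x named numeric vector holding exactly the 14 entries of
#'   [conductanceNames()] (any order; stored in canonical order)
#' @return named numeric vector of class `lp_conductances`
#' @export
conductanceSet <- function(x) {
  nms <- conductanceNames()
  if (is.null(names(x))) stop("conductance set must be named")
  missing <- setdiff(nms, names(x))
  if (length(missing))
    stop("missing conductance entries: ", paste(missing, collapse = ", "))
  extra <- setdiff(names(x), nms)
  if (length(extra))
    stop("unknown conductance entries: ", paste(extra, collapse = ", "))
  x <- x[nms]
  if (any(!is.finite(x))) stop("conductances must be finite")
  if (any(x < 0)) {
    bad <- nms[x < 0][1]
    stop(sprintf("conductances must be >= 0 (offending entry: %s)", bad))
  }
  structure(as.numeric(x), names = nms, class = "lp_conductances")
}

#' Four-compartment LP morphology constants
#'
#' Compartment capacitances, coupling resistors, and axon geometry of the
#' reduced LP model: axon initial segment, soma-primary neurite, secondary
#' neurites, tertiary neurites, coupled in a chain
#' axon --(r1 + r2)-- soma --(r3)-- secondary --(r4)-- tertiary.
#' Only r2 is rescaled by the axonal axial resistivity Ra
#' (control: Ra = 100 Ohm cm corresponds to r2 = 1.80e7 Ohm).
#'
#' A consistency note: the half-cable axial resistance of the stated axon
#' geometry, Ra*L/(2*pi*(d/2)^2) at Ra = 100 Ohm cm, is about 1.84e7 Ohm,
#' 2% from the tabulated 1.80e7 Ohm; the tabulated value is authoritative
#' and is what the Ra map is anchored to.
#'
#' @param capacitances nF, named after the four compartments
#' @param resistors Ohm, named r1..r4
#' @param axon_length,axon_diam um
#' @return an `lp_morphology` list
#' @export
lpMorphology <- function(capacitances = c(axon = 0.039, soma = 0.8,
                                          secondary = 3.74, tertiary = 5.50),
                         resistors = c(r1 = 2.50e5, r2 = 1.80e7,
                                       r3 = 1.13e6, r4 = 2.26e7),
                         axon_length = 354.5, axon_diam = 3.5) {
  stopifnot(length(capacitances) == 4, length(resistors) == 4)
  if (any(capacitances <= 0)) stop("capacitances must be positive")
  if (any(resistors <= 0)) stop("resistors must be positive")
  names(capacitances) <- COMPARTMENTS
  names(resistors) <- c("r1", "r2", "r3", "r4")
  structure(list(capacitances = capacitances, resistors = resistors,
                 axon_length = axon_length, axon_diam = axon_diam),
            class = "lp_morphology")
}

gateCols <- function(g) {
  if (is.null(g)) return(c(0, 1, 0, 1, 0, 0, 1, 1))
  c(g$vhalf, g$slope, g$tau$type, g$tau$c0, g$tau$amp, g$tau$vhalf,
    g$tau$k1, g$tau$k2)
}

chanRow <- function(comp, kin, g, erevOverride = NA) {
  row <- numeric(CH$NCOL)
  row[CH$COMP] <- comp
  row[CH$KIND] <- if (kin$kind == "ghk") 1 else 0
  row[CH$G] <- g
  row[CH$EREV] <- if (!is.na(erevOverride)) erevOverride else
    if (is.finite(kin$erev)) kin$erev else 0
  row[CH$P] <- kin$p
  row[CH$Q] <- kin$q
  row[CH$AVH:CH$AK2] <- gateCols(kin$act)
  row[CH$IVH:CH$IK2] <- gateCols(kin$inact)
  row[CH$CADEP] <- as.numeric(isTRUE(kin$cadep))
  row[CH$KD] <- kin$kd
  row[CH$CAO] <- kin$cao
  row[CH$TEMP] <- kin$temperature
  row[CH$Z] <- kin$z
  row
}

#' Assemble a four-compartment LP cell
#'
#' Places channels per compartment: the axon carries leak, Kd, A and Na; the
#' soma-primary, secondary and tertiary compartments each carry leak, MI, Kd,
#' A, KCa, the GHK calcium channel and h, with a single density parameter per
#' channel scaled by compartment membrane area (proportional to capacitance,
#' anchored at the soma-primary compartment). The three graded inhibitory
#' synapses are distributed over the secondary and tertiary neurites in
#' proportion to membrane area (optionally also the soma-primary
#' compartment).
#'
#' @param conductances a [conductanceSet()] (or named vector coercible to one)
#' @param morphology an [lpMorphology()]
#' @param registry kinetics registry, default [defaultKinetics()]; must cover
#'   channels Na, Kd, A, KCa, CaGHK, h, MI, leak
#' @param pool a [calciumPool()]; the current-to-concentration factor is
#'   rescaled per compartment inversely with capacitance (volume proxy)
#' @param eleak_axon axonal leak reversal, mV
#' @param syn_vthresh,syn_vscale graded-synapse activation parameters, mV
#' @param tau_syn_pd PD synapse time constant, ms (AB/PY are instantaneous)
#' @param include_soma_targets if TRUE the synapses also contact the
#'   soma-primary compartment (area-proportional split over three targets)
#' @param ra axonal axial resistivity, Ohm cm (control 100)
#' @return an `lp_cell` object
#' @export
buildCell <- function(conductances, morphology = lpMorphology(),
                      registry = defaultKinetics(), pool = calciumPool(),
                      eleak_axon = -60, syn_vthresh = -55, syn_vscale = 5,
                      tau_syn_pd = 50, include_soma_targets = FALSE,
                      ra = 100) {
  g <- conductanceSet(unclass(conductances))
  needed <- c("Na", "Kd", "A", "KCa", "CaGHK", "h", "MI", "leak")
  missing <- setdiff(needed, names(registry))
  if (length(missing))
    stop("kinetics registry lacks channels: ", paste(missing, collapse = ", "))
  validateKinetics(registry)

  caps <- morphology$capacitances
  scale <- caps[2:4] / caps["soma"]          # area scaling for g densities
  rows <- list(
    chanRow(0, registry$leak, g["g_leak_axon"], erevOverride = eleak_axon),
    chanRow(0, registry$Kd, g["g_Kd_axon"]),
    chanRow(0, registry$A, g["g_A_axon"]),
    chanRow(0, registry$Na, g["g_Na_axon"]))
  for (ci in 1:3) {
    sc <- scale[ci]
    rows <- c(rows, list(
      chanRow(ci, registry$leak, g["g_leak"] * sc),
      chanRow(ci, registry$MI, g["g_MI"] * sc),
      chanRow(ci, registry$Kd, g["g_Kd"] * sc),
      chanRow(ci, registry$A, g["g_A"] * sc),
      chanRow(ci, registry$KCa, g["g_KCa"] * sc),
      chanRow(ci, registry$CaGHK, g["p_Ca"] * sc),
      chanRow(ci, registry$h, g["g_h"] * sc)))
  }
  chanMat <- do.call(rbind, rows)

  # synaptic targets split by membrane area
  targets <- if (include_soma_targets) 1:3 else 2:3
  fr <- caps[targets + 1] / sum(caps[targets + 1])
  synPars <- list(AB = c(drive = 0, erev = -70, tau = 0, g = g[["g_synAB"]]),
                  PD = c(drive = 1, erev = -80, tau = tau_syn_pd, g = g[["g_synPD"]]),
                  PY = c(drive = 2, erev = -70, tau = 0, g = g[["g_synPY"]]))
  synRows <- list()
  for (sp in synPars) {
    for (k in seq_along(targets)) {
      synRows <- c(synRows, list(c(sp["drive"], targets[k], sp["g"] * fr[k],
                                   sp["erev"], syn_vthresh, syn_vscale,
                                   sp["tau"])))
    }
  }
  synMat <- do.call(rbind, synRows)
  dimnames(synMat) <- NULL

  # one calcium pool per calcium-bearing compartment; the flux factor scales
  # inversely with capacitance (volume proxy), anchored at the soma
  caMat <- cbind(1:3, pool$ca_rest, pool$tau_ca,
                 pool$f * caps["soma"] / caps[2:4])
  dimnames(caMat) <- NULL

  cell <- structure(list(
    morphology = morphology, conductances = g, registry = registry,
    pool = pool, capacitances = unname(caps), chanMat = chanMat,
    synMat = synMat, caMat = caMat, ra = NA_real_,
    eleak_axon = eleak_axon, syn_vthresh = syn_vthresh,
    syn_vscale = syn_vscale, tau_syn_pd = tau_syn_pd,
    include_soma_targets = include_soma_targets,
    edges = NULL), class = "lp_cell")
  setAxonalRa(cell, ra)
}

#' @export
print.lp_cell <- function(x, ...) {
  cat("<lp_cell> four-compartment LP model\n")
  cat(sprintf("  capacitances (nF): %s\n",
              paste(sprintf("%s=%.3g", COMPARTMENTS, x$capacitances),
                    collapse = ", ")))
  cat(sprintf("  axonal Ra: %g Ohm cm (r2 = %.3g Ohm)\n", x$ra, x$edges[1, 3] -
                x$morphology$resistors["r1"]))
  cat(sprintf("  %d channel placements, %d synaptic contacts, %d Ca pools\n",
              nrow(x$chanMat), nrow(x$synMat), nrow(x$caMat)))
  invisible(x)
}

#' Set the axonal axial resistivity
#'
#' Varying axonal Ra rescales only the axon-to-soma coupling resistor r2,
#' linearly and anchored at the control point (Ra = 100 Ohm cm corresponds to
#' r2 = 1.80e7 Ohm for the default morphology): `r2' = r2_control * ra / 100`.
#' The other resistors are left untouched, so neurite input resistance is
#' unchanged.
#'
#' @param cell an `lp_cell`
#' @param ra axial resistivity, Ohm cm; must lie in \[2, 500\] unless
#'   `override = TRUE`
#' @param override allow values outside the constrained range
#' @return the cell with updated coupling
#' @export
setAxonalRa <- function(cell, ra, override = FALSE) {
  stopifnot(inherits(cell, "lp_cell"))
  if (!override && (ra < 2 || ra > 500))
    stop("ra must lie in [2, 500] Ohm cm (use override = TRUE to explore wider)")
  if (ra <= 0) stop("ra must be positive")
  res <- cell$morphology$resistors
  r2 <- unname(res["r2"]) * ra / 100
  cell$edges <- cbind(c(0, 1, 2), c(1, 2, 3),
                      c(unname(res["r1"]) + r2, unname(res["r3"]),
                        unname(res["r4"])))
  cell$ra <- ra
  cell
}

#' State vector layout of a cell
#'
#' Fixed, documented ordering: the four voltages (axon, soma, secondary,
#' tertiary), then per channel placement (axon first, then soma, secondary,
#' tertiary) the activation gate m and, when present, the inactivation gate
#' h, then intracellular calcium per calcium-bearing compartment, then the
#' first-order synaptic gates (PD contacts).
#'
#' @param cell an `lp_cell`
#' @return character vector of state names
#' @export
stateNames <- function(cell) {
  labs <- c("leak", "Kd", "A", "Na")
  somaLabs <- c("leak", "MI", "Kd", "A", "KCa", "CaGHK", "h")
  perComp <- c(paste0(labs, "_axon"),
               unlist(lapply(c("soma", "sec", "ter"),
                             function(cn) paste0(somaLabs, "_", cn))))
  nms <- c("V_axon", "V_soma", "V_sec", "V_ter")
  for (r in seq_len(nrow(cell$chanMat))) {
    if (cell$chanMat[r, CH$P] > 0) nms <- c(nms, paste0("m_", perComp[r]))
    if (cell$chanMat[r, CH$Q] > 0) nms <- c(nms, paste0("h_", perComp[r]))
  }
  nms <- c(nms, paste0("ca_", c("soma", "sec", "ter")))
  nPD <- sum(cell$synMat[, SY$TAU] > 0)
  if (nPD > 0) nms <- c(nms, paste0("s_PD_", seq_len(nPD)))
  nms
}

#' Initial state of a cell
#'
#' All voltages at `v0`, gates at their steady state for `v0` (with the
#' calcium-dependent factor evaluated at resting calcium), calcium at rest,
#' synaptic gates at their steady state for a hyperpolarized presynaptic
#' baseline.
#'
#' @param cell an `lp_cell`
#' @param v0 initial membrane potential, mV
#' @param vpre0 presynaptic baseline used for the synaptic gates, mV
#' @return named numeric state vector matching [stateNames()]
#' @export
initState <- function(cell, v0 = -60, vpre0 = -80) {
  st <- rep(v0, 4)
  cm <- cell$chanMat
  for (r in seq_len(nrow(cm))) {
    if (cm[r, CH$P] > 0) {
      minf <- 1 / (1 + exp(-(v0 - cm[r, CH$AVH]) / cm[r, CH$AK]))
      if (cm[r, CH$CADEP] == 1) {
        rest <- cell$pool$ca_rest
        minf <- minf * rest / (rest + cm[r, CH$KD])
      }
      st <- c(st, minf)
    }
    if (cm[r, CH$Q] > 0)
      st <- c(st, 1 / (1 + exp(-(v0 - cm[r, CH$IVH]) / cm[r, CH$IK])))
  }
  st <- c(st, rep(cell$pool$ca_rest, nrow(cell$caMat)))
  nPD <- sum(cell$synMat[, SY$TAU] > 0)
  if (nPD > 0)
    st <- c(st, rep(synapticActivation(vpre0, cell$syn_vthresh,
                                       cell$syn_vscale), nPD))
  setNames(st, stateNames(cell))
}

#' Right-hand side of the cell ODE system (reference implementation)
#'
#' Plain-R evaluation of the full derivative vector,
#' `C_i dV_i/dt = -sum(I_ion,i) - sum(I_syn,i) + sum_j (V_j - V_i)/R_ij`,
#' gate relaxation `(x_inf - x)/tau`, first-order calcium pools and synaptic
#' gates. This is the ground-truth dynamical definition; the compiled
#' integrator advances the same equations with a semi-implicit scheme. Axial
#' current from i to j equals minus that from j to i by construction.
#'
#' @param cell an `lp_cell`
#' @param state numeric state vector ([stateNames()] order)
#' @param t time, ms
#' @param driveFun function of t returning the three presynaptic voltages
#'   `c(AB, PD, PY)` in mV
#' @return list: `dstate` (derivatives), plus per-compartment bookkeeping
#'   (`ionic`, `synaptic`, `axial`, in nA) for conservation checks
#' @export
cellRhs <- function(cell, state, t, driveFun) {
  if (any(!is.finite(state))) stop("non-finite state")
  cm <- cell$chanMat
  nst <- length(state)
  v <- state[1:4]
  gi <- 5L
  mIdx <- hIdx <- rep(NA_integer_, nrow(cm))
  for (r in seq_len(nrow(cm))) {
    if (cm[r, CH$P] > 0) { mIdx[r] <- gi; gi <- gi + 1L }
    if (cm[r, CH$Q] > 0) { hIdx[r] <- gi; gi <- gi + 1L }
  }
  caOff <- gi - 1L
  nca <- nrow(cell$caMat)
  sOff <- caOff + nca
  caOfComp <- setNames(rep(NA_integer_, 4), 0:3)
  for (k in seq_len(nca)) caOfComp[as.character(cell$caMat[k, CAM$COMP])] <- k

  dst <- numeric(nst)
  ionic <- synd <- axial <- numeric(4)
  ica <- numeric(4)

  for (r in seq_len(nrow(cm))) {
    comp <- cm[r, CH$COMP] + 1
    w <- 1
    if (!is.na(mIdx[r])) w <- w * state[mIdx[r]]^cm[r, CH$P]
    if (!is.na(hIdx[r])) w <- w * state[hIdx[r]]^cm[r, CH$Q]
    if (cm[r, CH$KIND] == 0) {
      ionic[comp] <- ionic[comp] + cm[r, CH$G] * w * (v[comp] - cm[r, CH$EREV])
    } else {
      k <- caOfComp[as.character(cm[r, CH$COMP])]
      cai <- state[caOff + k]
      I <- cppGhkCurrent(cm[r, CH$G], w, cai, cm[r, CH$CAO], v[comp],
                         cm[r, CH$TEMP], cm[r, CH$Z])
      ionic[comp] <- ionic[comp] + I
      ica[comp] <- ica[comp] + I
    }
  }

  vpre <- driveFun(t)
  sk <- 0L
  for (s in seq_len(nrow(cell$synMat))) {
    row <- cell$synMat[s, ]
    comp <- row[SY$COMP] + 1
    if (row[SY$TAU] > 0) {
      sk <- sk + 1L
      sval <- state[sOff + sk]
      sinf <- 1 / (1 + exp(-(vpre[row[SY$DRIVE] + 1] - row[SY$VTH]) / row[SY$VSC]))
      dst[sOff + sk] <- (sinf - sval) / row[SY$TAU]
    } else {
      sval <- 1 / (1 + exp(-(vpre[row[SY$DRIVE] + 1] - row[SY$VTH]) / row[SY$VSC]))
    }
    synd[comp] <- synd[comp] + row[SY$G] * sval * (v[comp] - row[SY$EREV])
  }

  for (e in seq_len(nrow(cell$edges))) {
    i <- cell$edges[e, 1] + 1; j <- cell$edges[e, 2] + 1
    gax <- 1 / (cell$edges[e, 3] / 1e6)  # uS
    Iij <- gax * (v[j] - v[i])           # current into i
    axial[i] <- axial[i] + Iij
    axial[j] <- axial[j] - Iij
  }

  dst[1:4] <- (-ionic - synd + axial) / cell$capacitances

  for (r in seq_len(nrow(cm))) {
    comp <- cm[r, CH$COMP] + 1
    if (!is.na(mIdx[r])) {
      rr <- cppGateInfTau(v[comp], cm[r, CH$AVH], cm[r, CH$AK], cm[r, CH$ATT],
                          cm[r, CH$AC0], cm[r, CH$AAMP], cm[r, CH$AVHT],
                          cm[r, CH$AK1], cm[r, CH$AK2])
      inf <- rr[1]
      if (cm[r, CH$CADEP] == 1) {
        k <- caOfComp[as.character(cm[r, CH$COMP])]
        cai <- state[caOff + k]
        inf <- inf * cai / (cai + cm[r, CH$KD])
      }
      dst[mIdx[r]] <- (inf - state[mIdx[r]]) / rr[2]
    }
    if (!is.na(hIdx[r])) {
      rr <- cppGateInfTau(v[comp], cm[r, CH$IVH], cm[r, CH$IK], cm[r, CH$ITT],
                          cm[r, CH$IC0], cm[r, CH$IAMP], cm[r, CH$IVHT],
                          cm[r, CH$IK1], cm[r, CH$IK2])
      dst[hIdx[r]] <- (rr[1] - state[hIdx[r]]) / rr[2]
    }
  }

  for (k in seq_len(nca)) {
    comp <- cell$caMat[k, CAM$COMP] + 1
    dst[caOff + k] <- (cell$caMat[k, CAM$REST] - state[caOff + k]) /
      cell$caMat[k, CAM$TAU] - cell$caMat[k, CAM$F] * ica[comp]
  }

  list(dstate = dst, ionic = ionic, synaptic = synd, axial = axial)
}
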