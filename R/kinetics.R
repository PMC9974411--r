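#' Gating-kinetics descriptions
#'
#' Each voltage-gated channel is described declaratively: a sigmoid steady
#' state per gate, `x_inf(V) = 1 / (1 + exp(-(V - vhalf)/slope))` (positive
#' slope for activation, negative for inactivation), integer exponents `p`
#' (activation) and `q` (inactivation, 0 for none), and a parametric time
#' constant that is either constant, sigmoid in V, or bell-shaped in V:
#'
#' * `constant`: `tau = c0`
#' * `sigmoid`:  `tau = c0 + amp / (1 + exp((V - vhalf)/k1))`
#' * `bell`:     `tau = c0 + amp / (exp((V - vhalf)/k1) + exp(-(V - vhalf)/k2))`
#'
#' All voltages in mV, time constants in ms.
#'
#' @param c0,amp,vhalf,k1,k2 time-constant parameters (see forms above)
#' @return A `tau_spec` list.
#' @seealso [defaultKinetics()], [gateRates()]
#' @export
tauConstant <- function(c0) {
  stopifnot(is.numeric(c0), c0 > 0)
  structure(list(type = 0L, c0 = c0, amp = 0, vhalf = 0, k1 = 1, k2 = 1),
            class = "tau_spec")
}

#' @rdname tauConstant
#' @export
tauSigmoid <- function(c0, amp, vhalf, k1) {
  structure(list(type = 1L, c0 = c0, amp = amp, vhalf = vhalf, k1 = k1, k2 = 1),
            class = "tau_spec")
}

#' @rdname tauConstant
#' @export
tauBell <- function(c0, amp, vhalf, k1, k2) {
  structure(list(type = 2L, c0 = c0, amp = amp, vhalf = vhalf, k1 = k1,
                 k2 = k2), class = "tau_spec")
}

#' Construct one gate description
#'
#' @param vhalf half-activation voltage, mV
#' @param slope slope factor, mV; positive for activation gates, negative for
#'   inactivation gates (sets the direction of the sigmoid)
#' @param tau a `tau_spec` from [tauConstant()], [tauSigmoid()] or [tauBell()]
#' @return a `gate_spec` list
#' @export
gateSpec <- function(vhalf, slope, tau) {
  if (!is.numeric(slope) || slope == 0)
    stop("gate slope must be nonzero (field 'slope')")
  if (!inherits(tau, "tau_spec")) stop("tau must be a tau_spec (field 'tau')")
  structure(list(vhalf = vhalf, slope = slope, tau = tau), class = "gate_spec")
}

#' Construct one channel kinetics entry
#'
#' @param name channel label, e.g. `"Na"`
#' @param kind `"ohmic"` or `"ghk"` (Goldman-Hodgkin-Katz calcium channel)
#' @param erev reversal potential, mV (ohmic channels only)
#' @param p,q integer gate exponents; `p = 0` means no activation gate (pure
#'   leak), `q = 0` no inactivation
#' @param act,inact `gate_spec` descriptions (NULL when the exponent is 0)
#' @param cadep logical; if TRUE the activation steady state is multiplied by
#'   the calcium occupancy `cai / (cai + kd)` (used by the KCa channel)
#' @param kd half-activation calcium concentration for `cadep`, mM
#' @param cao extracellular calcium, mM (ghk only)
#' @param temperature Kelvin (ghk only)
#' @param z ion valence (ghk only)
#' @return a `channel_kinetics` list
#' @export
channelKinetics <- function(name, kind = c("ohmic", "ghk"), erev = NA,
                            p = 1L, q = 0L, act = NULL, inact = NULL,
                            cadep = FALSE, kd = 3e-3, cao = 13,
                            temperature = 283.15, z = 2) {
  kind <- match.arg(kind)
  if (p < 0 || q < 0) stop("gate exponents must be >= 0 (fields 'p'/'q')")
  if (p > 0 && is.null(act)) stop("activation gate required when p > 0 (field 'act')")
  if (q > 0 && is.null(inact)) stop("inactivation gate required when q > 0 (field 'inact')")
  if (kind == "ohmic" && !is.finite(erev))
    stop("ohmic channel needs a finite reversal potential (field 'erev')")
  if (kind == "ghk") {
    if (cao <= 0) stop("extracellular calcium must be positive (field 'cao')")
    if (temperature <= 0) stop("temperature must be positive (field 'temperature')")
  }
  structure(list(name = name, kind = kind, erev = erev, p = as.integer(p),
                 q = as.integer(q), act = act, inact = inact, cadep = cadep,
                 kd = kd, cao = cao, temperature = temperature, z = z),
            class = "channel_kinetics")
}

#' Default gating-kinetics registry
#'
#' Kinetics in the lineage of published stomatogastric (STG) neuron models:
#' sigmoid steady states with sigmoid or bell time constants, `m^p h^q` gate
#' structure, a fast non-inactivating modulatory inward current (MI), a slow
#' hyperpolarization-activated inward current (h), an inactivating A current,
#' and a calcium-activated K current gated by both voltage and intracellular
#' calcium. Every value can be overridden, either programmatically or through
#' a registry file ([readKineticsRegistry()]), so an externally fitted
#' kinetics set can be dropped in without code changes.
#'
#' @return named list of `channel_kinetics` entries
#'   (Na, Kd, A, KCa, CaGHK, h, MI, leak)
#' @export
defaultKinetics <- function() {
  list(
    Na = channelKinetics("Na", "ohmic", erev = 50, p = 3L, q = 1L,
      act = gateSpec(-32, 5.29, tauSigmoid(1.32, -1.26, -120, -25)),
      inact = gateSpec(-46.3895, -5.18, tauBell(0.5, 6, -49.3895, 11, 11))),
    Kd = channelKinetics("Kd", "ohmic", erev = -80, p = 4L, q = 0L,
      act = gateSpec(-12.3, 11.8, tauSigmoid(7.2, -6.4, -28.3, -19.2))),
    A = channelKinetics("A", "ohmic", erev = -80, p = 3L, q = 1L,
      act = gateSpec(-27.2, 8.7, tauSigmoid(11.6, -10.4, -32.9, -15.2)),
      inact = gateSpec(-56.9, -4.9, tauSigmoid(38.6, -29.2, -38.9, -26.5))),
    KCa = channelKinetics("KCa", "ohmic", erev = -80, p = 1L, q = 0L,
      act = gateSpec(-28.3, 12.6, tauSigmoid(90.3, -75.1, -46.0, -22.7)),
      cadep = TRUE, kd = 2.03366e-3),
    CaGHK = channelKinetics("CaGHK", "ghk", p = 3L, q = 1L,
      act = gateSpec(-33.0, 8.1, tauBell(1.4, 7.0, -48, 10, 13)),
      inact = gateSpec(-60.0, -6.2, tauBell(60, 150, -60, 9, 16)),
      cao = 13, temperature = 283.15, z = 2),
    h = channelKinetics("h", "ohmic", erev = -20, p = 1L, q = 0L,
      act = gateSpec(-75.0, -5.5, tauSigmoid(272, 1499, -42.2, -8.73))),
    MI = channelKinetics("MI", "ohmic", erev = -10, p = 1L, q = 0L,
      act = gateSpec(-55.0, 5.0, tauConstant(6))),
    leak = channelKinetics("leak", "ohmic", erev = -50, p = 0L, q = 0L)
  )
}

#' Evaluate a gate's steady state and time constant
#'
#' @param gate a `gate_spec`
#' @param v membrane potential, mV (vectorised)
#' @return list with components `inf` (fraction in (0,1)) and `tau` (ms)
#' @export
gateRates <- function(gate, v) {
  stopifnot(inherits(gate, "gate_spec"), all(is.finite(v)))
  out <- vapply(v, function(vi) {
    cppGateInfTau(vi, gate$vhalf, gate$slope, gate$tau$type, gate$tau$c0,
                  gate$tau$amp, gate$tau$vhalf, gate$tau$k1, gate$tau$k2)
  }, numeric(2))
  list(inf = out[1, ], tau = out[2, ])
}

#' Validate a kinetics registry
#'
#' Checks structural invariants for every entry: nonzero slopes, nonnegative
#' exponents, steady states inside (0,1) and strictly positive time constants
#' over V in \[-120, 60\] mV. Errors name the offending channel and field.
#'
#' @param registry named list of `channel_kinetics`
#' @param vgrid voltages at which positivity of tau is checked
#' @return invisibly TRUE
#' @export
validateKinetics <- function(registry, vgrid = seq(-120, 60, by = 1)) {
  if (is.null(names(registry)) || any(names(registry) == ""))
    stop("kinetics registry entries must be named")
  for (nm in names(registry)) {
    ch <- registry[[nm]]
    if (!inherits(ch, "channel_kinetics"))
      stop(sprintf("registry entry '%s' is not a channel_kinetics", nm))
    for (side in c("act", "inact")) {
      g <- ch[[side]]
      if (is.null(g)) next
      r <- gateRates(g, vgrid)
      if (any(r$tau <= 0))
        stop(sprintf("channel '%s': %s tau not strictly positive on [-120, 60] mV (field '%s.tau')",
                     nm, side, side))
      if (any(r$inf <= 0 | r$inf >= 1))
        stop(sprintf("channel '%s': %s steady state leaves (0,1) (field '%s')",
                     nm, side, side))
    }
  }
  invisible(TRUE)
}

# ---- registry file format: "[Channel]" blocks of key = value lines ---------

fmtTau <- function(tau) {
  lbl <- c("constant", "sigmoid", "bell")[tau$type + 1L]
  paste(lbl, tau$c0, tau$amp, tau$vhalf, tau$k1, tau$k2)
}

parseTau <- function(txt, where) {
  parts <- strsplit(trimws(txt), "\\s+")[[1]]
  type <- match(parts[1], c("constant", "sigmoid", "bell")) - 1L
  if (is.na(type))
    stop(sprintf("%s: unknown tau form '%s' (expected constant/sigmoid/bell)",
                 where, parts[1]))
  vals <- as.numeric(parts[-1])
  if (anyNA(vals) || length(vals) < 5)
    stop(sprintf("%s: tau needs 5 numeric parameters", where))
  structure(list(type = type, c0 = vals[1], amp = vals[2], vhalf = vals[3],
                 k1 = vals[4], k2 = vals[5]), class = "tau_spec")
}

#' Read / write a kinetics registry file
#'
#' Plain-text key-value format: one `[ChannelName]` block per channel with
#' `key = value` lines (`kind`, `erev`, `p`, `q`, `act.vhalf`, `act.slope`,
#' `act.tau`, `inact.*`, `cadep`, `kd`, `cao`, `temperature`, `z`). Tau lines
#' hold the form name followed by its five parameters. Validation errors name
#' the offending channel and field.
#'
#' @param path file path
#' @param registry named list of `channel_kinetics` (for writing)
#' @return `readKineticsRegistry`: a validated registry list
#' @export
readKineticsRegistry <- function(path) {
  lines <- readLines(path)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  registry <- list()
  cur <- NULL
  kv <- list()
  flush <- function(cur, kv) {
    if (is.null(cur)) return(NULL)
    g <- function(k, default = NULL) if (!is.null(kv[[k]])) kv[[k]] else default
    num <- function(k, default = NA) {
      v <- g(k)
      if (is.null(v)) return(default)
      x <- suppressWarnings(as.numeric(v))
      if (is.na(x)) stop(sprintf("channel '%s': field '%s' is not numeric", cur, k))
      x
    }
    p <- as.integer(num("p", 1)); q <- as.integer(num("q", 0))
    mkGate <- function(side) {
      vh <- num(paste0(side, ".vhalf")); sl <- num(paste0(side, ".slope"))
      tl <- g(paste0(side, ".tau"))
      if (is.na(vh) || is.na(sl) || is.null(tl))
        stop(sprintf("channel '%s': incomplete gate description (field '%s')", cur, side))
      gateSpec(vh, sl, parseTau(tl, sprintf("channel '%s' %s.tau", cur, side)))
    }
    channelKinetics(cur, kind = g("kind", "ohmic"), erev = num("erev", NA),
                    p = p, q = q,
                    act = if (p > 0) mkGate("act") else NULL,
                    inact = if (q > 0) mkGate("inact") else NULL,
                    cadep = identical(g("cadep", "0"), "1"),
                    kd = num("kd", 3e-3), cao = num("cao", 13),
                    temperature = num("temperature", 283.15), z = num("z", 2))
  }
  for (ln in lines) {
    if (grepl("^\\[.+\\]$", ln)) {
      if (!is.null(cur)) registry[[cur]] <- flush(cur, kv)
      cur <- sub("^\\[(.+)\\]$", "\\1", ln)
      kv <- list()
    } else {
      m <- regmatches(ln, regexec("^([A-Za-z0-9_.]+)\\s*=\\s*(.*)$", ln))[[1]]
      if (length(m) != 3)
        stop(sprintf("malformed registry line: '%s'", ln))
      kv[[m[2]]] <- m[3]
    }
  }
  if (!is.null(cur)) registry[[cur]] <- flush(cur, kv)
  validateKinetics(registry)
  registry
}

#' @rdname readKineticsRegistry
#' @export
writeKineticsRegistry <- function(registry, path) {
  out <- character(0)
  for (nm in names(registry)) {
    ch <- registry[[nm]]
    out <- c(out, sprintf("[%s]", nm), sprintf("kind = %s", ch$kind))
    if (is.finite(ch$erev)) out <- c(out, sprintf("erev = %.10g", ch$erev))
    out <- c(out, sprintf("p = %d", ch$p), sprintf("q = %d", ch$q))
    for (side in c("act", "inact")) {
      g <- ch[[side]]
      if (is.null(g)) next
      out <- c(out,
               sprintf("%s.vhalf = %.10g", side, g$vhalf),
               sprintf("%s.slope = %.10g", side, g$slope),
               sprintf("%s.tau = %s", side, fmtTau(g$tau)))
    }
    if (isTRUE(ch$cadep)) out <- c(out, "cadep = 1", sprintf("kd = %.10g", ch$kd))
    if (ch$kind == "ghk")
      out <- c(out, sprintf("cao = %.10g", ch$cao),
               sprintf("temperature = %.10g", ch$temperature),
               sprintf("z = %.10g", ch$z))
    out <- c(out, "")
  }
  writeLines(out, path)
  invisible(path)
}
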