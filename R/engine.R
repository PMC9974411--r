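#' Solver configuration
#'
#' Fixed-step semi-implicit integration: backward Euler on the voltages
#' (exact solve of the coupled 4-compartment linear system each step, with
#' open fractions frozen over the step) and exponential integrators for
#' gates, calcium pools and synaptic activation — unconditionally stable for
#' this stiff system, in the manner of compartmental simulators.
#'
#' @param dt step, ms
#' @param max_settle_cycles most drive cycles integrated while waiting for a
#'   periodic axonal spike pattern
#' @param analysis_cycles cycles returned (and re-verified) after settling
#' @param settle_tol_ms phase-aligned spike-time tolerance for "same pattern"
#' @param record_every record state every this many steps
#' @param use_tables use piecewise-linear gate tables (0.05 mV grid) inside
#'   the compiled engine; turn off for validation against the exact rates
#' @return a `solver_config` list
#' @export
solverConfig <- function(dt = 0.05, max_settle_cycles = 30L,
                         analysis_cycles = 4L, settle_tol_ms = 5,
                         record_every = 4L, use_tables = TRUE) {
  if (dt <= 0) stop("dt must be positive")
  if (analysis_cycles < 2) stop("analysis_cycles must be >= 2")
  if (max_settle_cycles < analysis_cycles)
    stop("max_settle_cycles must be >= analysis_cycles")
  structure(list(dt = dt, max_settle_cycles = as.integer(max_settle_cycles),
                 analysis_cycles = as.integer(analysis_cycles),
                 settle_tol_ms = settle_tol_ms,
                 record_every = as.integer(record_every),
                 use_tables = isTRUE(use_tables)), class = "solver_config")
}

#' Integrate a cell for a fixed duration
#'
#' @param cell an `lp_cell`
#' @param drive an `lp_drive` (or NULL for no synaptic drive)
#' @param duration ms (> 0; 0 returns only the initial state)
#' @param cfg a [solverConfig()]
#' @param state0 initial state, default [initState()]
#' @return an `lp_trace`: time grid (ms), voltage matrix (mV, columns
#'   V_axon, V_soma, V_sec, V_ter), calcium (mM), final state
#' @export
simulate <- function(cell, drive, duration, cfg = solverConfig(),
                     state0 = initState(cell)) {
  stopifnot(inherits(cell, "lp_cell"), duration >= 0)
  if (is.null(drive)) {
    dm <- matrix(-80, nrow = 1, ncol = 3)  # silent presynaptic partners
  } else {
    dm <- driveMatrix(drive, cfg$dt)
  }
  nsteps <- round(duration / cfg$dt)
  res <- cppSimulate(cellLowLevel(cell), dm, cfg$dt, nsteps,
                     as.numeric(state0), cfg$record_every, 0, cfg$use_tables)
  colnames(res$V) <- c("V_axon", "V_soma", "V_sec", "V_ter")
  structure(list(time = res$time, V = res$V, cai = res$cai,
                 state = setNames(res$state, stateNames(cell)),
                 dt = cfg$dt, settled = NA), class = "lp_trace")
}

cellLowLevel <- function(cell) {
  list(capacitances = cell$capacitances, edges = cell$edges,
       chanMat = cell$chanMat, synMat = cell$synMat, caMat = cell$caMat)
}

#' Integrate whole drive cycles to a steady firing pattern
#'
#' Runs the cell cycle by cycle until the axonal spike pattern of two
#' consecutive cycles matches (same spike count and phase-aligned spike
#' times within `settle_tol_ms`), or `max_settle_cycles` is exhausted, then
#' records `analysis_cycles` further cycles. The settled flag is set only if
#' the periodicity criterion also holds across the recorded window.
#'
#' @param cell an `lp_cell`
#' @param drive an `lp_drive` with known period
#' @param cfg a [solverConfig()]
#' @param classifierCfg spike threshold/refractory used for the settle
#'   criterion, a [classifierConfig()]
#' @param state0 initial state
#' @return an `lp_steady` object: `settled`, `cycles_to_settle`, `time`,
#'   `V`, axonal `spikes` (ms, within the analysis window), `period`,
#'   `analysis_cycles`, final `state`
#' @export
runToSteadyState <- function(cell, drive, cfg = solverConfig(),
                             classifierCfg = classifierConfig(),
                             state0 = initState(cell)) {
  stopifnot(inherits(cell, "lp_cell"), inherits(drive, "lp_drive"))
  dm <- driveMatrix(drive, cfg$dt)
  res <- cppRunToSteadyState(cellLowLevel(cell), dm, cfg$dt,
                             cfg$max_settle_cycles, cfg$analysis_cycles,
                             cfg$settle_tol_ms, classifierCfg$threshold,
                             classifierCfg$refractory, as.numeric(state0),
                             cfg$record_every, cfg$use_tables)
  colnames(res$V) <- c("V_axon", "V_soma", "V_sec", "V_ter")
  structure(list(settled = res$settled,
                 cycles_to_settle = res$cycles_to_settle, time = res$time,
                 V = res$V, spikes = as.numeric(res$spikes),
                 period = res$period, analysis_cycles = res$analysis_cycles,
                 state = setNames(res$state, stateNames(cell)),
                 dt = cfg$dt), class = "lp_steady")
}

#' @export
print.lp_trace <- function(x, ...) {
  cat(sprintf("<lp_trace> %d samples over %.1f ms (dt = %g ms)\n",
              length(x$time), max(x$time), x$dt))
  invisible(x)
}

#' @export
print.lp_steady <- function(x, ...) {
  cat(sprintf("<lp_steady> %s after %d cycle(s); %d axonal spikes over %d analysis cycles (period %g ms)\n",
              if (isTRUE(x$settled)) "settled" else "NOT settled",
              x$cycles_to_settle, length(x$spikes), x$analysis_cycles,
              x$period))
  invisible(x)
}

#' Export a trace as a plain-text table
#'
#' @param trace an `lp_trace` or `lp_steady`
#' @param path output file; tab-separated with a documented header
#'   (time, V_axon, V_soma, V_sec, V_ter)
#' @export
writeTrace <- function(trace, path) {
  df <- data.frame(time = trace$time, trace$V, check.names = FALSE)
  write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
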