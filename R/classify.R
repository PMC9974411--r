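#' Classifier configuration
#'
#' @param threshold axonal spike detection threshold, mV (axonal spikes
#'   overshoot 0 mV; somatic spikes are attenuated)
#' @param refractory minimum spike separation, ms
#' @param gap_threshold maximal within-burst inter-spike interval, ms
#'   (well below the drive period, well above within-burst ISIs)
#' @param tonic_occupancy fraction of cycle phase bins that must contain
#'   spikes for the tonic label
#' @param n_phase_bins phase bins per cycle for the tonic criterion
#' @param db_voltage sustained-depolarization criterion for the
#'   depolarization-block label, mV
#' @return a `classifier_config` list
#' @export
classifierConfig <- function(threshold = 0, refractory = 2,
                             gap_threshold = 100, tonic_occupancy = 0.8,
                             n_phase_bins = 20L, db_voltage = -40) {
  if (refractory < 0) stop("refractory must be >= 0")
  if (gap_threshold <= 0) stop("gap_threshold must be positive")
  structure(list(threshold = threshold, refractory = refractory,
                 gap_threshold = gap_threshold,
                 tonic_occupancy = tonic_occupancy,
                 n_phase_bins = as.integer(n_phase_bins),
                 db_voltage = db_voltage), class = "classifier_config")
}

#' Detect spikes in a voltage trace
#'
#' One spike per upward threshold crossing, with sub-sample timing by linear
#' interpolation; crossings within the refractory window of the previous
#' spike are ignored.
#'
#' @param v voltage samples, mV (uniform grid)
#' @param dt sample interval, ms
#' @param t0 time of the first sample, ms
#' @param threshold detection threshold, mV
#' @param refractory minimum separation, ms
#' @return an `lp_spiketrain`: strictly increasing spike times (ms)
#' @export
detectSpikes <- function(v, dt, t0 = 0, threshold = 0, refractory = 2) {
  if (any(!is.finite(v))) stop("trace must be finite")
  times <- as.numeric(cppDetectSpikes(v, dt, t0, threshold, refractory))
  structure(list(times = times, threshold = threshold,
                 refractory = refractory), class = "lp_spiketrain")
}

#' Group spikes into bursts within drive cycles
#'
#' Within each cycle window, maximal runs of spikes whose consecutive
#' inter-spike intervals stay below `gap_threshold` form bursts; a spike
#' belongs to exactly one burst.
#'
#' @param times spike times, ms (or an `lp_spiketrain`)
#' @param cycle_bounds monotone vector of window boundaries, ms (length
#'   n_cycles + 1)
#' @param gap_threshold ms
#' @return list of length n_cycles; each element a list of numeric vectors
#'   (one per burst)
#' @export
segmentBursts <- function(times, cycle_bounds, gap_threshold = 100) {
  if (inherits(times, "lp_spiketrain")) times <- times$times
  if (is.unsorted(cycle_bounds, strictly = TRUE))
    stop("cycle bounds must be strictly increasing")
  ncyc <- length(cycle_bounds) - 1
  out <- vector("list", ncyc)
  for (c in seq_len(ncyc)) {
    sp <- times[times >= cycle_bounds[c] & times < cycle_bounds[c + 1]]
    if (length(sp) == 0) { out[[c]] <- list(); next }
    brk <- which(diff(sp) >= gap_threshold)
    starts <- c(1, brk + 1)
    ends <- c(brk, length(sp))
    out[[c]] <- lapply(seq_along(starts),
                       function(k) sp[starts[k]:ends[k]])
  }
  out
}

#' Classify a settled trace into one of five firing patterns
#'
#' Labels, in the order tested:
#' * `non_spiking` / `depolarization_block`: zero spikes; block if the
#'   axonal membrane potential stays above the depolarization criterion for
#'   most of the window (spike currents inactivated by sustained
#'   depolarization), otherwise non-spiking.
#' * `aperiodic_spiking`: spikes but the pattern never settled.
#' * `tonic_spiking`: spikes occupy at least `tonic_occupancy` of the cycle
#'   phase bins, i.e. firing persists through the inhibited phases.
#' * `rebound_bursting`: settled, exactly one burst per cycle, at least two
#'   spikes per burst, equal per-cycle spike counts across the window.
#' * `aperiodic_spiking` otherwise.
#'
#' @param ss an `lp_steady` from [runToSteadyState()] (at least 2 cycles)
#' @param cfg a [classifierConfig()]
#' @return an `lp_pattern`: `label`, `spikes_per_burst` (mean; defined only
#'   when bursting), `per_cycle_counts`, `bursts`
#' @export
classifyPattern <- function(ss, cfg = classifierConfig()) {
  stopifnot(inherits(ss, "lp_steady"))
  if (ss$analysis_cycles < 2) stop("need at least 2 analysis cycles")
  period <- ss$period
  ncyc <- ss$analysis_cycles
  spikes <- ss$spikes

  lab <- NULL
  spb <- NA_real_
  bursts <- NULL
  counts <- integer(ncyc)

  if (length(spikes) == 0) {
    vax <- ss$V[, "V_axon"]
    fracDepol <- mean(vax > cfg$db_voltage)
    lab <- if (fracDepol >= 0.5) "depolarization_block" else "non_spiking"
  } else if (!isTRUE(ss$settled)) {
    lab <- "aperiodic_spiking"
  } else {
    # phase-bin occupancy pooled over cycles
    phase <- (spikes %% period) / period
    bins <- unique(pmin(floor(phase * cfg$n_phase_bins), cfg$n_phase_bins - 1))
    occupancy <- length(bins) / cfg$n_phase_bins
    bounds <- seq(0, ncyc * period, by = period)
    bursts <- segmentBursts(spikes, bounds, cfg$gap_threshold)
    nb <- lengths(bursts)
    counts <- vapply(bursts, function(b) length(unlist(b)), integer(1))
    if (occupancy >= cfg$tonic_occupancy) {
      lab <- "tonic_spiking"
    } else if (all(nb == 1) && all(counts == counts[1]) && counts[1] >= 2) {
      lab <- "rebound_bursting"
      spb <- mean(vapply(bursts, function(b) length(b[[1]]), integer(1)))
    } else {
      lab <- "aperiodic_spiking"
    }
  }

  structure(list(label = lab, spikes_per_burst = spb,
                 per_cycle_counts = counts, bursts = bursts,
                 settled = ss$settled), class = "lp_pattern")
}

#' Mean spikes per burst of a bursting pattern
#'
#' @param pattern an `lp_pattern` with label `rebound_bursting`
#' @return arithmetic mean spike count per burst over the analysis cycles
#' @export
spikesPerBurst <- function(pattern) {
  stopifnot(inherits(pattern, "lp_pattern"))
  if (pattern$label != "rebound_bursting")
    stop("spikes per burst is defined only for rebound-bursting patterns")
  pattern$spikes_per_burst
}

#' @export
print.lp_pattern <- function(x, ...) {
  cat(sprintf("<lp_pattern> %s%s\n", x$label,
              if (!is.na(x$spikes_per_burst))
                sprintf(" (%.2f spikes/burst)", x$spikes_per_burst) else ""))
  invisible(x)
}
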