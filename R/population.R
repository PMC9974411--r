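#' Parametric pyloric drive waveforms
#'
#' Periodic presynaptic voltage traces for the AB, PD and PY inputs: raised-
#' cosine-edged pulses from a hyperpolarized baseline to a depolarized peak,
#' exactly periodic and C1-smooth. AB and PD share a window (their slow waves
#' and spikes are synchronized); the PY window precedes it within each cycle.
#' Phase 0 is anchored at the release from the PD/AB inhibition, so each
#' drive cycle contains one rebound window at its start.
#'
#' @param period cycle period, ms
#' @param py_window,pd_window start/end of each pulse as fractions of the
#'   cycle (0 <= start < end <= 1); AB equals PD
#' @param baseline,peak envelope voltages, mV
#' @param smoothing raised-cosine edge width, ms
#' @return an `lp_drive` object
#' @export
pyloricDrive <- function(period = 1000, py_window = c(0.55, 0.875),
                         pd_window = c(0.85, 1.00), baseline = -70,
                         peak = -10, smoothing = 25) {
  if (period <= 0) stop("period must be positive")
  for (w in list(py_window, pd_window))
    if (!(w[1] >= 0 && w[1] < w[2] && w[2] <= 1))
      stop("window fractions must satisfy 0 <= start < end <= 1")
  if (smoothing <= 0) stop("smoothing must be positive")
  if (2 * smoothing > min(diff(py_window), diff(pd_window)) * period)
    stop("smoothing wider than a pulse: contradictory windows")
  structure(list(period = period, windows = list(AB = pd_window,
                                                 PD = pd_window,
                                                 PY = py_window),
                 baseline = baseline, peak = peak, smoothing = smoothing,
                 sampled = NULL), class = "lp_drive")
}

#' Drive from sampled presynaptic traces
#'
#' Wraps externally supplied periodic voltage traces (e.g. smoothed
#' recordings) as a drive. Each trace is a two-column time/voltage table
#' covering one period; traces are resampled onto the solver grid by linear
#' interpolation.
#'
#' @param period cycle period, ms
#' @param ab,pd,py two-column matrices or data frames (time ms, voltage mV)
#' @return an `lp_drive` object
#' @export
sampledDrive <- function(period, ab, pd, py) {
  chk <- function(x, nm) {
    x <- as.matrix(x)
    if (ncol(x) != 2) stop(sprintf("%s trace must have two columns", nm))
    if (any(x[, 1] < 0 | x[, 1] > period))
      stop(sprintf("%s trace times must lie in [0, period]", nm))
    x
  }
  structure(list(period = period, windows = NULL, baseline = NA, peak = NA,
                 smoothing = NA,
                 sampled = list(AB = chk(ab, "AB"), PD = chk(pd, "PD"),
                                PY = chk(py, "PY"))), class = "lp_drive")
}

# periodic raised-cosine envelope, value in [0, 1]
driveEnvelope <- function(t, period, window, smoothing) {
  a <- window[1] * period
  b <- window[2] * period
  tm <- t %% period
  # distance handling with wrap-around for edges touching the boundary
  env <- numeric(length(tm))
  up <- function(x) 0.5 * (1 - cos(pi * x / smoothing))
  for (i in seq_along(tm)) {
    x <- tm[i]
    # unwrap x to the window's frame
    for (shift in c(-period, 0, period)) {
      xx <- x + shift
      if (xx >= a && xx <= b) {
        d <- min(xx - a, b - xx)
        env[i] <- if (d >= smoothing) 1 else up(d)
        break
      }
    }
  }
  env
}

#' Sample a drive onto a solver time grid
#'
#' @param drive an `lp_drive`
#' @param dt step, ms; the period must be an integer number of steps
#' @return matrix with `period/dt` rows and columns AB, PD, PY (mV)
#' @export
driveMatrix <- function(drive, dt) {
  stopifnot(inherits(drive, "lp_drive"))
  n <- round(drive$period / dt)
  if (abs(n * dt - drive$period) > 1e-9)
    stop("period must be an integer multiple of dt")
  tt <- (seq_len(n) - 1) * dt
  if (!is.null(drive$sampled)) {
    out <- sapply(drive$sampled, function(tr) {
      approx(tr[, 1], tr[, 2], xout = tt, rule = 2)$y
    })
  } else {
    out <- sapply(drive$windows, function(w) {
      drive$baseline + (drive$peak - drive$baseline) *
        driveEnvelope(tt, drive$period, w, drive$smoothing)
    })
  }
  colnames(out) <- c("AB", "PD", "PY")
  out
}

#' @export
print.lp_drive <- function(x, ...) {
  cat(sprintf("<lp_drive> period %g ms, %s\n", x$period,
              if (is.null(x$sampled)) sprintf(
                "parametric (baseline %g mV, peak %g mV, PY %.2f-%.2f, PD/AB %.2f-%.2f)",
                x$baseline, x$peak, x$windows$PY[1], x$windows$PY[2],
                x$windows$PD[1], x$windows$PD[2]) else "sampled traces"))
  invisible(x)
}

#' Default synthetic sampling intervals for the 14 conductances
#'
#' Per-channel uniform sampling intervals used to generate the synthetic
#' parent population. These are this package's own calibration — chosen so
#' that random sampling followed by the rebound-bursting screen retains
#' parents at a practical rate around a working LP-like model — and are
#' documented as synthetic, not as any deposited database's ranges.
#'
#' @param halfwidth relative half-width of each interval around the
#'   reference value (0.35 gives \[0.65, 1.35\] times the reference); wider
#'   boxes make the desired pattern rarer under random sampling
#' @return 14 x 2 matrix (columns min, max; rows [conductanceNames()])
#' @export
syntheticSamplingIntervals <- function(halfwidth = 0.35) {
  base <- referenceConductances()
  lo <- pmax(0, (1 - halfwidth)) * base
  hi <- (1 + halfwidth) * base
  m <- cbind(min = lo, max = hi)
  rownames(m) <- conductanceNames()
  m
}

#' A reference rebound-bursting conductance set
#'
#' The calibration anchor of the synthetic population: a hand-tuned set that
#' produces a clean rebound burst under the default pyloric drive at control
#' coupling.
#'
#' @return an [conductanceSet()]
#' @export
referenceConductances <- function() {
  conductanceSet(c(
    g_leak_axon = 0.00906033, g_Kd_axon = 3.87938, g_A_axon = 0.667749,
    g_Na_axon = 31.3239, g_leak = 0.037494, g_MI = 0.0416375,
    g_Kd = 1.18418, g_A = 1.01386, g_KCa = 4.60412, p_Ca = 1.31191e-5,
    g_h = 0.404372, g_synAB = 0.372599, g_synPD = 0.413109,
    g_synPY = 0.635245))
}

#' Sample random conductance sets
#'
#' Each of the 14 channels is drawn independently and uniformly from its
#' sampling interval; reproducible from the seed.
#'
#' @param n population size (>= 1)
#' @param intervals 14 x 2 matrix of per-channel (min, max), rows named after
#'   [conductanceNames()]; default [syntheticSamplingIntervals()]
#' @param seed integer RNG seed
#' @return data frame with n rows and 14 named columns
#' @export
sampleConductanceSets <- function(n, intervals = syntheticSamplingIntervals(),
                                  seed = 1L) {
  stopifnot(n >= 1)
  nms <- conductanceNames()
  if (!all(nms %in% rownames(intervals)))
    stop("intervals must have one row per conductance name")
  intervals <- intervals[nms, , drop = FALSE]
  if (any(!is.finite(intervals)) || any(intervals < 0) ||
      any(intervals[, 2] < intervals[, 1]))
    stop("sampling intervals must be finite, nonnegative and ordered")
  set.seed(as.integer(seed))
  out <- sapply(seq_len(14), function(j) {
    runif(n, intervals[j, 1], intervals[j, 2])
  })
  out <- as.data.frame(out)
  names(out) <- nms
  out
}

#' Screen a candidate population for rebound bursting
#'
#' Simulates each candidate to steady state under the drive at control
#' morphology and keeps those classified as rebound bursters. Labels of the
#' rejected candidates and the hit rate are reported.
#'
#' @param candidates data frame of conductance sets (14 named columns)
#' @param drive an `lp_drive`
#' @param cfg a [solverConfig()]
#' @param classifierCfg a [classifierConfig()]
#' @param spb_range optional 2-vector; when given, retained parents must also
#'   have spikes per burst within this closed range
#' @param ... passed to [buildCell()]
#' @return list with `parents` (retained rows), `labels` (all candidates),
#'   `spikes_per_burst` (all candidates, NA unless bursting), `hit_rate`
#' @export
screenPopulation <- function(candidates, drive, cfg = solverConfig(),
                             classifierCfg = classifierConfig(),
                             spb_range = NULL, ...) {
  if (nrow(candidates) == 0) stop("candidates must be non-empty")
  labels <- character(nrow(candidates))
  spb <- rep(NA_real_, nrow(candidates))
  for (i in seq_len(nrow(candidates))) {
    cell <- buildCell(unlist(candidates[i, conductanceNames()]), ...)
    ss <- runToSteadyState(cell, drive, cfg)
    pat <- classifyPattern(ss, classifierCfg)
    labels[i] <- pat$label
    if (pat$label == "rebound_bursting") spb[i] <- pat$spikes_per_burst
  }
  keep <- labels == "rebound_bursting"
  if (!is.null(spb_range))
    keep <- keep & !is.na(spb) & spb >= spb_range[1] & spb <= spb_range[2]
  list(parents = candidates[keep, , drop = FALSE], labels = labels,
       spikes_per_burst = spb, hit_rate = mean(keep))
}

#' Per-channel extremes over a parent population
#'
#' @param parents data frame with the 14 conductance columns (>= 2 rows)
#' @return 14 x 2 matrix (min, max), rows named after [conductanceNames()]
#' @export
conductanceBounds <- function(parents) {
  if (nrow(parents) < 2)
    stop("degenerate bounds: need at least 2 parents")
  nms <- conductanceNames()
  m <- cbind(min = vapply(parents[nms], min, numeric(1)),
             max = vapply(parents[nms], max, numeric(1)))
  rownames(m) <- nms
  m
}

#' Read / write model parameter tables
#'
#' CSV with one row per model and the 14 named conductance columns
#' ([conductanceNames()]); an optional `id` column is preserved, unknown
#' extra columns are accepted with a warning and ignored. Values round-trip
#' bit-exactly through [writeParameterTable()].
#'
#' @param path file path
#' @return data frame of validated conductance sets
#' @export
loadParameterTable <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- read.csv(path, check.names = FALSE)
  nms <- conductanceNames()
  missing <- setdiff(nms, names(df))
  if (length(missing))
    stop("parameter table lacks column(s): ", paste(missing, collapse = ", "))
  extra <- setdiff(names(df), c(nms, "id"))
  if (length(extra)) {
    warning("ignoring unknown column(s): ", paste(extra, collapse = ", "))
    df <- df[, setdiff(names(df), extra), drop = FALSE]
  }
  for (nm in nms) {
    bad <- which(df[[nm]] < 0 | !is.finite(df[[nm]]))
    if (length(bad))
      stop(sprintf("negative or non-finite %s at row %d", nm, bad[1]))
  }
  df[, c(intersect("id", names(df)), nms), drop = FALSE]
}

#' @rdname loadParameterTable
#' @param parents data frame of conductance sets
#' @export
writeParameterTable <- function(parents, path) {
  nms <- conductanceNames()
  stopifnot(all(nms %in% names(parents)))
  keep <- c(intersect("id", names(parents)), nms)
  df <- parents[, keep, drop = FALSE]
  # full precision so values survive the round trip bit-exactly
  for (nm in nms) df[[nm]] <- sprintf("%.17g", df[[nm]])
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Packaged synthetic fixture populations
#'
#' Pre-screened synthetic parents (all rebound bursters at control
#' morphology under the default drive) and a coupling-elite subset that in
#' addition keeps rebound bursting when the axonal Ra is set to 2, 100 and
#' 500 Ohm cm. Both were produced by this package's own screen and are
#' shipped so examples and tests do not depend on screening compute.
#' Synthetic: these are not any deposited database's models.
#'
#' @return data frame of conductance sets (with `id` column)
#' @export
fixtureParents <- function() {
  loadParameterTable(system.file("extdata", "parents_synthetic.csv",
                                 package = "lpneuro", mustWork = TRUE))
}

#' @rdname fixtureParents
#' @export
fixtureElites <- function() {
  loadParameterTable(system.file("extdata", "elites_synthetic.csv",
                                 package = "lpneuro", mustWork = TRUE))
}
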