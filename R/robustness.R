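#' Deterministic per-trial seed
#'
#' Counter-based seeding keyed by (experiment seed, parent id, trial index),
#' so any child model can be regenerated in isolation and trial order is
#' irrelevant. The mix stays below 2^31.
#'
#' @param seed master experiment seed (integer)
#' @param parent_id integer parent identifier
#' @param trial trial index (1-based)
#' @param stream extra stream separator for independent experiments
#' @return integer seed
#' @export
trialSeed <- function(seed, parent_id, trial, stream = 0L) {
  x <- (as.double(seed) %% 2147483647) * 48271 %% 2147483647
  x <- (x + as.double(parent_id) * 2246822519 + as.double(trial) * 3266489917 +
          as.double(stream) * 668265263) %% 2147483647
  as.integer(x)
}

#' Randomly perturb all (or some) conductances of a parent model
#'
#' Each selected channel x is shifted by
#' `u_x * variation_range * (g_x,max - g_x,min)` with `u_x ~ Uniform(-1, 1)`
#' drawn independently per channel; a conductance that would become negative
#' is set to zero.
#'
#' @param parent a [conductanceSet()] (or named vector)
#' @param variation_range fraction >= 0 (e.g. 0.1 for +/-10%)
#' @param bounds 14 x 2 matrix of per-channel (min, max) from
#'   [conductanceBounds()]
#' @param seed integer seed for the draw (see [trialSeed()]); ignored when
#'   `u` is given
#' @param u optional named vector of per-channel draws in \[-1, 1\]
#'   (deterministic replay)
#' @param channels names of the channels to perturb (default: all 14)
#' @return perturbed `lp_conductances` (the child model)
#' @export
perturbConductances <- function(parent, variation_range, bounds, seed = NULL,
                                u = NULL, channels = conductanceNames()) {
  parent <- conductanceSet(unclass(parent))
  if (variation_range < 0) stop("variation_range must be >= 0")
  nms <- conductanceNames()
  unknown <- setdiff(channels, nms)
  if (length(unknown)) stop("unknown channel(s): ", paste(unknown, collapse = ", "))
  if (!all(nms %in% rownames(bounds)))
    stop("bounds must cover all 14 channels")
  if (is.null(u)) {
    if (is.null(seed)) stop("either seed or u must be given")
    set.seed(as.integer(seed))
    u <- setNames(runif(14, -1, 1), nms)
  } else {
    u <- u[nms]
    if (anyNA(u) || any(abs(u) > 1)) stop("u must cover all channels, within [-1, 1]")
  }
  delta <- u * variation_range * (bounds[nms, "max"] - bounds[nms, "min"])
  child <- unclass(parent)
  child[channels] <- pmax(0, child[channels] + delta[channels])
  conductanceSet(child)
}

defaultEvalFun <- function(drive, cfg, classifierCfg, ra, ...) {
  force(drive); force(cfg); force(classifierCfg); force(ra)
  function(g) {
    cell <- buildCell(g, ra = ra, ...)
    classifyPattern(runToSteadyState(cell, drive, cfg, classifierCfg),
                    classifierCfg)
  }
}

#' Robustness ratio of one parent model
#'
#' Runs `m` independent perturb-simulate-classify trials and reports the
#' fraction of child models classified as rebound bursters. The parent's own
#' classification is recorded separately and never enters the ratio. Every
#' trial is replayable from its recorded seed.
#'
#' @param parent a conductance set
#' @param m number of trials (>= 1)
#' @param variation_range perturbation range fraction
#' @param bounds per-channel (min, max) matrix
#' @param drive an `lp_drive`
#' @param cfg a [solverConfig()]
#' @param classifierCfg a [classifierConfig()]
#' @param seed master seed
#' @param parent_id integer id entering the per-trial seeds
#' @param ra axonal axial resistivity for all trials, Ohm cm
#' @param channels channels to perturb (default all 14)
#' @param stream seed stream separator
#' @param evalFun optional function(conductances) -> `lp_pattern`, replacing
#'   the simulate+classify pipeline (for calibration and estimator tests)
#' @param classify_parent also classify the unperturbed parent
#' @param ... passed to [buildCell()]
#' @return an `lp_robustness` row: `ratio`, `n_bursting`, `m`, per-trial
#'   `labels`, `spikes_per_burst`, `seeds`, and the parent's own label
#' @export
robustnessRatio <- function(parent, m, variation_range, bounds, drive,
                            cfg = solverConfig(),
                            classifierCfg = classifierConfig(), seed = 1L,
                            parent_id = 1L, ra = 100,
                            channels = conductanceNames(), stream = 0L,
                            evalFun = NULL, classify_parent = FALSE, ...) {
  if (m < 1) stop("m must be >= 1")
  parent <- conductanceSet(unclass(parent))
  if (is.null(evalFun))
    evalFun <- defaultEvalFun(drive, cfg, classifierCfg, ra, ...)
  labels <- character(m)
  spb <- rep(NA_real_, m)
  seeds <- integer(m)
  for (tr in seq_len(m)) {
    seeds[tr] <- trialSeed(seed, parent_id, tr, stream)
    child <- perturbConductances(parent, variation_range, bounds,
                                 seed = seeds[tr], channels = channels)
    pat <- evalFun(child)
    labels[tr] <- pat$label
    if (pat$label == "rebound_bursting") spb[tr] <- pat$spikes_per_burst
  }
  nb <- sum(labels == "rebound_bursting")
  parentLabel <- NA_character_
  parentSpb <- NA_real_
  if (classify_parent) {
    pp <- evalFun(parent)
    parentLabel <- pp$label
    if (pp$label == "rebound_bursting") parentSpb <- pp$spikes_per_burst
  }
  structure(list(parent_id = parent_id, m = m,
                 variation_range = variation_range, ra = ra,
                 n_bursting = nb, ratio = nb / m, labels = labels,
                 spikes_per_burst = spb, seeds = seeds, master_seed = seed,
                 parent_label = parentLabel, parent_spb = parentSpb),
            class = "lp_robustness")
}

#' @export
print.lp_robustness <- function(x, ...) {
  cat(sprintf("<lp_robustness> parent %s: %d/%d children bursting (ratio %.3f) at range +/-%g%%, Ra %g\n",
              x$parent_id, x$n_bursting, x$m, x$ratio,
              100 * x$variation_range, x$ra))
  invisible(x)
}

#' Select elite parents
#'
#' Elites are parents whose children are all rebound bursters at the +/-10%
#' range (ratio exactly 1) and whose own and whose children's spikes per
#' burst lie within `spb_range`.
#'
#' @param reports list of `lp_robustness` rows at the +/-10% range, with the
#'   parent classified (`classify_parent = TRUE`)
#' @param spb_range closed spikes-per-burst interval, default 3 to 11
#' @return logical vector marking the elite reports
#' @export
selectElite <- function(reports, spb_range = c(3, 11)) {
  if (length(reports) == 0) return(logical(0))
  vapply(reports, function(r) {
    stopifnot(inherits(r, "lp_robustness"))
    r$ratio == 1 &&
      !is.na(r$parent_spb) &&
      r$parent_spb >= spb_range[1] && r$parent_spb <= spb_range[2] &&
      all(!is.na(r$spikes_per_burst)) &&
      all(r$spikes_per_burst >= spb_range[1] &
            r$spikes_per_burst <= spb_range[2])
  }, logical(1))
}

#' Sensitivity of the robustness ratio to a single channel
#'
#' Identical to [robustnessRatio()] except that only the named conductance
#' is perturbed; returns one mean-ratio curve over the variation ranges.
#'
#' @param parents data frame of conductance sets
#' @param channel one of [conductanceNames()]
#' @param variation_ranges numeric vector of range fractions
#' @param bounds per-channel (min, max)
#' @param m trials per parent per range
#' @inheritParams robustnessRatio
#' @return data frame (variation_range, mean_ratio, channel) plus per-parent
#'   ratios in `attr(, "ratios")`
#' @export
singleChannelSensitivity <- function(parents, channel, variation_ranges,
                                     bounds, m, drive, cfg = solverConfig(),
                                     classifierCfg = classifierConfig(),
                                     seed = 1L, ra = 100, evalFun = NULL,
                                     ...) {
  if (!channel %in% conductanceNames())
    stop("unknown channel: ", channel)
  ratios <- matrix(NA_real_, nrow(parents), length(variation_ranges))
  for (i in seq_len(nrow(parents))) {
    for (j in seq_along(variation_ranges)) {
      rep <- robustnessRatio(unlist(parents[i, conductanceNames()]), m,
                             variation_ranges[j], bounds, drive, cfg,
                             classifierCfg, seed = seed, parent_id = i,
                             ra = ra, channels = channel,
                             stream = 100L + j, evalFun = evalFun, ...)
      ratios[i, j] <- rep$ratio
    }
  }
  out <- data.frame(channel = channel, variation_range = variation_ranges,
                    mean_ratio = colMeans(ratios))
  attr(out, "ratios") <- ratios
  out
}

#' Axial-resistivity sweep
#'
#' Classifies each parent at every Ra value on the grid, with no conductance
#' perturbation: only the axon-to-soma coupling changes.
#'
#' @param parents data frame of conductance sets
#' @param ra_grid Ra values, Ohm cm (within \[2, 500\])
#' @param drive an `lp_drive`
#' @param cfg,classifierCfg solver and classifier configurations
#' @param ... passed to [buildCell()]
#' @return data frame with one row per (parent, ra): `parent`, `ra`,
#'   `label`, `spikes_per_burst`
#' @export
raSweep <- function(parents, ra_grid, drive, cfg = solverConfig(),
                    classifierCfg = classifierConfig(), ...) {
  rows <- list()
  for (i in seq_len(nrow(parents))) {
    g <- unlist(parents[i, conductanceNames()])
    for (ra in ra_grid) {
      cell <- buildCell(g, ra = ra, ...)
      pat <- classifyPattern(runToSteadyState(cell, drive, cfg,
                                              classifierCfg), classifierCfg)
      rows[[length(rows) + 1]] <-
        data.frame(parent = i, ra = ra, label = pat$label,
                   spikes_per_burst = pat$spikes_per_burst)
    }
  }
  do.call(rbind, rows)
}

#' Default Ra grid
#'
#' 5 Ohm cm steps from 2 to 100 plus coarser points up to 500.
#' @return numeric vector of Ra values, Ohm cm
#' @export
defaultRaGrid <- function() {
  c(2, seq(5, 100, by = 5), 125, 150, 200, 300, 500)
}

#' Burster-persistence exceptions on an Ra sweep
#'
#' Over the strong-coupling side of the grid (2 to 100 Ohm cm), a parent
#' that bursts at a smaller Ra is expected to keep bursting at larger Ra;
#' exceptions (burster at some Ra, non-burster at a larger Ra within the
#' interval) are counted and reported per parent.
#'
#' @param sweep result of [raSweep()]
#' @param ra_max upper bound of the interval examined, Ohm cm
#' @return data frame of exceptions (parent, ra_burst, ra_fail); zero rows
#'   when persistence is perfectly monotone
#' @export
persistenceExceptions <- function(sweep, ra_max = 100) {
  out <- list()
  for (p in unique(sweep$parent)) {
    sub <- sweep[sweep$parent == p & sweep$ra <= ra_max, ]
    sub <- sub[order(sub$ra), ]
    burst <- sub$label == "rebound_bursting"
    # one exception per non-bursting Ra that has a bursting Ra below it
    for (k in which(!burst)) {
      below <- which(burst & seq_along(burst) < k)
      if (length(below))
        out[[length(out) + 1]] <- data.frame(parent = p,
                                             ra_burst = sub$ra[max(below)],
                                             ra_fail = sub$ra[k])
    }
  }
  if (length(out)) do.call(rbind, out)
  else data.frame(parent = integer(0), ra_burst = numeric(0),
                  ra_fail = numeric(0))
}

#' Robustness ratio across Ra values
#'
#' Evaluates [robustnessRatio()] for each elite at each Ra and each
#' variation range; fresh perturbation draws are used per condition (seeds
#' logged). Elites that are not rebound bursters at some listed Ra are
#' excluded from that Ra with a logged reason.
#'
#' @param elites data frame of conductance sets
#' @param ra_values Ra values, Ohm cm
#' @param variation_ranges range fractions
#' @param m trials per condition
#' @inheritParams robustnessRatio
#' @return data frame (parent, ra, variation_range, ratio, parent_label);
#'   excluded conditions carry `ratio = NA` and the parent's actual label
#' @export
robustnessVsRa <- function(elites, ra_values, variation_ranges, m, bounds,
                           drive, cfg = solverConfig(),
                           classifierCfg = classifierConfig(), seed = 1L,
                           evalFun = NULL, ...) {
  rows <- list()
  for (i in seq_len(nrow(elites))) {
    g <- unlist(elites[i, conductanceNames()])
    for (ra in ra_values) {
      ef <- if (is.null(evalFun)) NULL else evalFun
      # parent must itself burst at this Ra to enter the comparison
      if (is.null(ef)) {
        cell <- buildCell(g, ra = ra, ...)
        ppat <- classifyPattern(runToSteadyState(cell, drive, cfg,
                                                 classifierCfg),
                                classifierCfg)
      } else {
        ppat <- ef(conductanceSet(g))
      }
      for (j in seq_along(variation_ranges)) {
        if (ppat$label != "rebound_bursting") {
          rows[[length(rows) + 1]] <-
            data.frame(parent = i, ra = ra,
                       variation_range = variation_ranges[j],
                       ratio = NA_real_, parent_label = ppat$label)
          next
        }
        rep <- robustnessRatio(g, m, variation_ranges[j], bounds, drive,
                               cfg, classifierCfg, seed = seed,
                               parent_id = i, ra = ra,
                               stream = 1000L * j + round(ra),
                               evalFun = ef, ...)
        rows[[length(rows) + 1]] <-
          data.frame(parent = i, ra = ra,
                     variation_range = variation_ranges[j],
                     ratio = rep$ratio, parent_label = ppat$label)
      }
    }
  }
  do.call(rbind, rows)
}
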