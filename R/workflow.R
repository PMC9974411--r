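#' Experiment configuration
#'
#' Bundles everything the two experiment drivers need: the population source
#' (a data frame of parents or a parameter-table path), variation ranges,
#' trial counts, the Ra grid, and the solver/classifier settings. The master
#' seed is recorded in every output.
#'
#' @param population data frame of conductance sets, or a path to a
#'   parameter table ([loadParameterTable()])
#' @param variation_ranges perturbation range fractions
#' @param m trials per parent per condition
#' @param ra_values Ra values for the coupling experiment, Ohm cm
#' @param seed master seed
#' @param drive an `lp_drive`
#' @param solver a [solverConfig()]
#' @param classifier a [classifierConfig()]
#' @param bounds optional per-channel bounds; default: computed from the
#'   population
#' @param outdir output directory for CSV reports and the manifest
#' @return an `lp_experiment_config`
#' @export
experimentConfig <- function(population, variation_ranges = c(0.1, 0.5, 1.0),
                             m = 50L, ra_values = c(2, 100, 500), seed = 1L,
                             drive = pyloricDrive(),
                             solver = solverConfig(),
                             classifier = classifierConfig(), bounds = NULL,
                             outdir = tempfile("lpneuro_run_")) {
  if (is.character(population)) population <- loadParameterTable(population)
  if (!is.data.frame(population) || nrow(population) == 0)
    stop("population must be a non-empty data frame or table path")
  if (is.null(bounds)) bounds <- conductanceBounds(population)
  structure(list(population = population,
                 variation_ranges = variation_ranges, m = as.integer(m),
                 ra_values = ra_values, seed = as.integer(seed),
                 drive = drive, solver = solver, classifier = classifier,
                 bounds = bounds, outdir = outdir),
            class = "lp_experiment_config")
}

# rolling polynomial hash (mod a 31-bit prime) over the serialized
# configuration; provenance tag in every output
configHash <- function(cfg) {
  bytes <- serialize(cfg[c("variation_ranges", "m", "ra_values", "seed")],
                     NULL, version = 2)
  h <- 17
  for (b in as.integer(bytes)) h <- (h * 31 + b) %% 2147483629
  sprintf("%08x", h)
}

writeManifest <- function(cfg, path, extra = list()) {
  man <- c(list(package = "lpneuro",
                version = as.character(utils::packageVersion("lpneuro")),
                seed = cfg$seed, m = cfg$m,
                variation_ranges = cfg$variation_ranges,
                ra_values = cfg$ra_values,
                n_parents = nrow(cfg$population),
                config_hash = configHash(cfg)), extra)
  jsonlite::write_json(man, path, auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(path)
}

#' Run the conductance-noise experiment
#'
#' For every parent and every variation range, computes the robustness ratio
#' (fraction of child models that are rebound bursters) and writes
#' per-parent ratios, histogram bin counts, and a run manifest with the
#' seeds and a configuration hash. Re-running with the same configuration
#' and master seed reproduces the files byte for byte.
#'
#' @param cfg an [experimentConfig()]
#' @param evalFun optional pattern evaluator override (see
#'   [robustnessRatio()])
#' @return invisibly, a list with the `ratios` data frame, `histogram` data
#'   frame and output paths
#' @export
runNoiseExperiment <- function(cfg, evalFun = NULL) {
  stopifnot(inherits(cfg, "lp_experiment_config"))
  dir.create(cfg$outdir, showWarnings = FALSE, recursive = TRUE)
  pop <- cfg$population
  rows <- list()
  for (i in seq_len(nrow(pop))) {
    g <- unlist(pop[i, conductanceNames()])
    for (j in seq_along(cfg$variation_ranges)) {
      vr <- cfg$variation_ranges[j]
      # seed stream matches robustnessVsRa at the control coupling, so a
      # coupling experiment restricted to Ra = 100 reproduces these ratios
      rep <- robustnessRatio(g, cfg$m, vr, cfg$bounds, cfg$drive,
                             cfg$solver, cfg$classifier, seed = cfg$seed,
                             parent_id = i, stream = 1000L * j + 100L,
                             evalFun = evalFun)
      rows[[length(rows) + 1]] <-
        data.frame(parent = i, variation_range = vr, m = cfg$m,
                   n_bursting = rep$n_bursting, ratio = rep$ratio)
    }
  }
  ratios <- do.call(rbind, rows)

  breaks <- seq(0, 1, by = 0.1)
  hist_rows <- list()
  for (vr in cfg$variation_ranges) {
    r <- ratios$ratio[ratios$variation_range == vr]
    # left-closed bins, with ratio = 1 landing in the top bin [0.9, 1]
    cnt <- vapply(seq_len(length(breaks) - 1), function(k) {
      if (k == length(breaks) - 1) sum(r >= breaks[k] & r <= breaks[k + 1])
      else sum(r >= breaks[k] & r < breaks[k + 1])
    }, numeric(1))
    hist_rows[[length(hist_rows) + 1]] <-
      data.frame(variation_range = vr, bin_lo = breaks[-length(breaks)],
                 bin_hi = breaks[-1], count = cnt)
  }
  histogram <- do.call(rbind, hist_rows)

  hash <- configHash(cfg)
  ratios$config_hash <- hash
  histogram$config_hash <- hash
  pr <- file.path(cfg$outdir, "ratios.csv")
  ph <- file.path(cfg$outdir, "histogram.csv")
  pm <- file.path(cfg$outdir, "manifest.json")
  write.csv(ratios, pr, row.names = FALSE, quote = FALSE)
  write.csv(histogram, ph, row.names = FALSE, quote = FALSE)
  writeManifest(cfg, pm, list(experiment = "noise"))
  invisible(list(ratios = ratios, histogram = histogram,
                 files = c(pr, ph, pm)))
}

#' Run the axonal-coupling experiment
#'
#' Produces the coupling sweep table (per-parent label and spikes per burst
#' at every Ra, no conductance perturbation) and the robustness-vs-Ra table
#' (per-parent child-burster ratio at every Ra and variation range), with a
#' manifest. `ra_values = 100` alone reduces the ratio table to the noise
#' experiment's output.
#'
#' @inheritParams runNoiseExperiment
#' @return invisibly, a list with `sweep` and `ratios` data frames and paths
#' @export
runRaExperiment <- function(cfg, evalFun = NULL) {
  stopifnot(inherits(cfg, "lp_experiment_config"))
  dir.create(cfg$outdir, showWarnings = FALSE, recursive = TRUE)
  pop <- cfg$population
  sweep <- if (is.null(evalFun)) {
    raSweep(pop, cfg$ra_values, cfg$drive, cfg$solver, cfg$classifier)
  } else {
    rows <- list()
    for (i in seq_len(nrow(pop))) {
      for (ra in cfg$ra_values) {
        pat <- evalFun(conductanceSet(unlist(pop[i, conductanceNames()])))
        rows[[length(rows) + 1]] <-
          data.frame(parent = i, ra = ra, label = pat$label,
                     spikes_per_burst = pat$spikes_per_burst)
      }
    }
    do.call(rbind, rows)
  }
  ratios <- robustnessVsRa(pop, cfg$ra_values, cfg$variation_ranges, cfg$m,
                           cfg$bounds, cfg$drive, cfg$solver,
                           cfg$classifier, seed = cfg$seed,
                           evalFun = evalFun)
  hash <- configHash(cfg)
  sweep$config_hash <- hash
  ratios$config_hash <- hash
  ps <- file.path(cfg$outdir, "ra_sweep.csv")
  pr <- file.path(cfg$outdir, "ra_ratios.csv")
  pm <- file.path(cfg$outdir, "manifest.json")
  write.csv(sweep, ps, row.names = FALSE, quote = FALSE)
  write.csv(ratios, pr, row.names = FALSE, quote = FALSE)
  writeManifest(cfg, pm, list(experiment = "ra"))
  invisible(list(sweep = sweep, ratios = ratios, files = c(ps, pr, pm)))
}

#' Check that report files share one configuration hash
#'
#' @param paths CSV report files carrying a `config_hash` column
#' @return the common hash, or an error naming the mismatching file
#' @export
checkReportHashes <- function(paths) {
  hashes <- vapply(paths, function(p) {
    df <- read.csv(p, nrows = 1)
    as.character(df$config_hash[1])
  }, character(1))
  if (length(unique(hashes)) > 1)
    stop("mixed configuration hashes: ",
         paste(basename(paths), hashes, sep = "=", collapse = ", "))
  unique(hashes)
}
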