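test_that("perturbation follows u * range * (gmax - gmin) with zero-clipping", {
  parent <- referenceConductances()
  bounds <- fixtureBounds()
  # range 0: exact identity
  child0 <- perturbConductances(parent, 0, bounds, seed = 5)
  expect_equal(unclass(child0), unclass(parent))
  # forced clipping via an explicit draw
  u <- setNames(rep(0, 14), conductanceNames())
  u["g_MI"] <- -0.9
  b <- bounds; b["g_MI", ] <- c(0, 10)
  p <- unclass(parent); p["g_MI"] <- 0.01
  child <- perturbConductances(conductanceSet(p), 1.0, b, u = u)
  expect_equal(unname(child["g_MI"]), 0)
  # the other channels are untouched by a zero draw
  expect_equal(child[names(child) != "g_MI"], p[names(p) != "g_MI"],
               ignore_attr = TRUE)
  # fixed-seed oracle: reproduce the generator sequence independently
  seed <- trialSeed(42, 3, 7)
  got <- perturbConductances(parent, 0.25, bounds, seed = seed)
  set.seed(seed)
  uref <- runif(14, -1, 1)
  ref <- pmax(0, unclass(parent) + uref * 0.25 * (bounds[, 2] - bounds[, 1]))
  expect_equal(unclass(got), ref, ignore_attr = TRUE)
  expect_error(perturbConductances(parent, 0.1, bounds[1:5, ], seed = 1),
               "bounds")
  expect_error(perturbConductances(parent, 0.1, bounds, seed = 1,
                                   channels = "g_bogus"), "unknown")
})

test_that("children stay inside the per-channel perturbation envelope", {
  parent <- referenceConductances()
  bounds <- fixtureBounds()
  delta <- 0.3 * (bounds[, 2] - bounds[, 1])
  for (k in 1:200) {
    child <- perturbConductances(parent, 0.3, bounds, seed = k)
    expect_true(all(child >= pmax(0, unclass(parent) - delta) - 1e-12))
    expect_true(all(child <= unclass(parent) + delta + 1e-12))
  }
})

test_that("the perturbation draws are uniform on [-1, 1]", {
  parent <- referenceConductances()
  bounds <- fixtureBounds()
  width <- bounds[, 2] - bounds[, 1]
  u <- vapply(1:10000, function(k) {
    child <- perturbConductances(parent, 0.05, bounds, seed = k,
                                 channels = "g_Kd")
    (child[["g_Kd"]] - parent[["g_Kd"]]) / (0.05 * width[["g_Kd"]])
  }, numeric(1))
  expect_true(all(abs(u) <= 1))
  ks <- suppressWarnings(ks.test(u, "punif", -1, 1))
  expect_gt(ks$p.value, 1e-3)
  expect_lt(abs(mean(u)), 0.03)
})

test_that("per-trial seeds are deterministic, distinct and 32-bit safe", {
  s <- trialSeed(1, 2, 3)
  expect_identical(s, trialSeed(1, 2, 3))
  grid <- expand.grid(p = 1:20, t = 1:50)
  seeds <- mapply(trialSeed, 7, grid$p, grid$t)
  expect_equal(anyDuplicated(seeds), 0)
  expect_true(all(seeds >= 0 & seeds < 2^31))
  expect_false(trialSeed(1, 2, 3) == trialSeed(1, 2, 3, stream = 1))
})

# deterministic stand-in classifier: bursts unless the child crosses a fixed
# hyperplane, so ratios have a known truth without simulation
mkStubEval <- function(pBurst = NULL) {
  function(g) {
    x <- sum(unclass(g)) * 1e4
    frac <- x - floor(x)
    burst <- if (is.null(pBurst)) TRUE else frac < pBurst
    structure(list(label = if (burst) "rebound_bursting" else "non_spiking",
                   spikes_per_burst = if (burst) 5 else NA_real_),
              class = "lp_pattern")
  }
}

test_that("the ratio estimator is unbiased with binomial spread", {
  parent <- referenceConductances()
  bounds <- fixtureBounds()
  p <- 0.7
  ratios <- vapply(1:150, function(seed) {
    robustnessRatio(parent, 20, 0.5, bounds, drive = NULL, seed = seed,
                    evalFun = mkStubEval(p))$ratio
  }, numeric(1))
  expect_lt(abs(mean(ratios) - p), 3 * sqrt(p * (1 - p) / 20 / 150))
  expect_lt(abs(var(ratios) - p * (1 - p) / 20), 0.01)
  # replay: identical seed, identical report
  r1 <- robustnessRatio(parent, 15, 0.5, bounds, NULL, seed = 9,
                        evalFun = mkStubEval(p))
  r2 <- robustnessRatio(parent, 15, 0.5, bounds, NULL, seed = 9,
                        evalFun = mkStubEval(p))
  expect_identical(r1$labels, r2$labels)
  expect_identical(r1$seeds, r2$seeds)
  expect_equal(r1$ratio, r1$n_bursting / r1$m)
  expect_error(robustnessRatio(parent, 0, 0.1, bounds, NULL, seed = 1), "m")
})

test_that("elite selection applies the ratio and spikes-per-burst criteria", {
  mkRep <- function(ratio, pspb, cspb) {
    structure(list(ratio = ratio, parent_spb = pspb, m = length(cspb),
                   spikes_per_burst = cspb), class = "lp_robustness")
  }
  reports <- list(
    mkRep(1.0, 5, c(4, 5, 6)),     # elite
    mkRep(0.99, 5, c(4, 5, 6)),    # ratio below 1
    mkRep(1.0, 12, c(4, 5, 6)),    # parent bursts too long
    mkRep(1.0, 5, c(4, 12, 6)),    # a child bursts too long
    mkRep(1.0, 2, c(4, 5, 6)))     # parent below the band
  expect_equal(selectElite(reports), c(TRUE, FALSE, FALSE, FALSE, FALSE))
  expect_equal(selectElite(list()), logical(0))
})

test_that("single-channel sensitivity perturbs only the named conductance", {
  parents <- fixtureParents()[1:3, ]
  bounds <- fixtureBounds()
  seen <- list()
  recorder <- function(g) {
    seen[[length(seen) + 1]] <<- unclass(g)
    structure(list(label = "rebound_bursting", spikes_per_burst = 5),
              class = "lp_pattern")
  }
  out <- singleChannelSensitivity(parents, "g_h", c(0, 0.5), bounds, m = 4,
                                  drive = NULL, seed = 2, evalFun = recorder)
  expect_equal(out$mean_ratio, c(1, 1))
  ref <- unlist(parents[1, conductanceNames()])
  kids <- do.call(rbind, seen[1:4])
  other <- setdiff(conductanceNames(), "g_h")
  for (k in 1:4) expect_equal(kids[k, other], ref[other])
  expect_error(singleChannelSensitivity(parents, "g_zz", 0.1, bounds, 2, NULL),
               "unknown channel")
})

test_that("persistence exceptions are counted once per failure", {
  sweep <- data.frame(parent = rep(1:2, each = 4),
                      ra = rep(c(10, 20, 50, 100), 2),
                      label = c("rebound_bursting", "non_spiking",
                                "rebound_bursting", "rebound_bursting",
                                rep("rebound_bursting", 4)),
                      spikes_per_burst = 4)
  ex <- persistenceExceptions(sweep)
  expect_equal(nrow(ex), 1)
  expect_equal(ex$parent, 1)
  expect_equal(ex$ra_burst, 10)
  expect_equal(ex$ra_fail, 20)
})

test_that("robustness-vs-Ra excludes non-bursting parents with a reason", {
  elites <- fixtureParents()[1:2, ]
  bounds <- fixtureBounds()
  flaky <- function(g) {
    # second parent has a distinctive g_Na_axon; mark it non-bursting
    bad <- abs(g[["g_Na_axon"]] - elites$g_Na_axon[2]) < 1e-9
    structure(list(label = if (bad) "non_spiking" else "rebound_bursting",
                   spikes_per_burst = if (bad) NA_real_ else 4),
              class = "lp_pattern")
  }
  out <- robustnessVsRa(elites, c(2, 100), c(0, 0.1), m = 3, bounds,
                        drive = NULL, seed = 4, evalFun = flaky)
  expect_equal(nrow(out), 2 * 2 * 2)
  bad <- out[out$parent == 2, ]
  expect_true(all(is.na(bad$ratio)))
  expect_true(all(bad$parent_label == "non_spiking"))
  good <- out[out$parent == 1 & out$variation_range == 0, ]
  expect_true(all(good$ratio == 1))   # range 0 reproduces the parent
})
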