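test_that("spike detection interpolates crossings and honours refractoriness", {
  # constant trace: nothing
  expect_equal(detectSpikes(rep(-60, 100), 0.1)$times, numeric(0))
  # three clean crossings of 0 mV with known sub-sample times
  dt <- 0.1
  tt <- seq(0, 30, by = dt)
  v <- -60 + 70 * (sin(2 * pi * tt / 10) > 0.5) - 10 * (tt %% 1)
  v <- -60 + 80 * pmax(0, sin(2 * pi * tt / 10))   # smooth humps, 3 periods
  sp <- detectSpikes(v, dt, threshold = 0, refractory = 2)
  expect_equal(length(sp$times), 3)
  # analytic crossing: -60 + 80 sin(2 pi t / 10) = 0 at t = (10/2/pi) asin(.75)
  t0 <- 10 / (2 * pi) * asin(60 / 80)
  expect_lt(abs(sp$times[1] - t0), dt)
  expect_equal(diff(sp$times), c(10, 10), tolerance = 0.02)
  # double-crossing ripple inside the refractory window counts once
  vr <- rep(-60, 200)
  vr[100:110] <- c(5, -1, 6, -2, 7, 5, 4, 3, -5, -20, -40)
  spr <- detectSpikes(vr, 0.1, threshold = 0, refractory = 2)
  expect_equal(length(spr$times), 1)
  expect_error(detectSpikes(c(1, NA, 2), 0.1), "finite")
})

test_that("spike detection equals a brute-force scan on random traces", {
  bruteForce <- function(v, dt, thr, refr) {
    out <- numeric(0)
    last <- -Inf
    for (i in 2:length(v)) {
      if (v[i - 1] < thr && v[i] >= thr) {
        t <- (i - 2 + (thr - v[i - 1]) / (v[i] - v[i - 1])) * dt
        if (t - last >= refr) { out <- c(out, t); last <- t }
      }
    }
    out
  }
  set.seed(99)
  for (k in 1:40) {
    v <- -20 + cumsum(rnorm(400, sd = 4))
    thr <- runif(1, -20, 0)
    refr <- runif(1, 0, 3)
    expect_equal(detectSpikes(v, 0.1, threshold = thr, refractory = refr)$times,
                 bruteForce(v, 0.1, thr, refr))
  }
})

test_that("burst segmentation splits on the ISI gap within cycles", {
  times <- cumsum(c(5, 10, 10, 500, 10, 10))
  b <- segmentBursts(times, c(0, 1000), gap_threshold = 100)
  expect_equal(length(b[[1]]), 2)
  expect_equal(lengths(b[[1]]), c(3L, 3L))
  expect_equal(segmentBursts(numeric(0), c(0, 1000))[[1]], list())
  # one spike per cycle: one singleton burst each
  b2 <- segmentBursts(c(100, 1100, 2100), c(0, 1000, 2000, 3000))
  expect_equal(lengths(b2), c(1L, 1L, 1L))
  expect_equal(lengths(b2[[1]]), 1L)
  # spikes are never shared between bursts
  expect_equal(sort(unlist(b[[1]])), sort(times))
  expect_error(segmentBursts(times, c(1000, 0)), "increasing")
  # invariance under a uniform shift of spikes and bounds
  b3 <- segmentBursts(times + 123.4, c(0, 1000) + 123.4, 100)
  expect_equal(unlist(b3[[1]]) - 123.4, unlist(b[[1]]))
})

test_that("the five-way pattern taxonomy follows the printed definitions", {
  # clean rebound bursts: 5 spikes early in each of 4 cycles
  sp <- as.vector(outer(c(20, 35, 50, 65, 80), (0:3) * 1000, "+"))
  pat <- classifyPattern(fakeSteady(sp))
  expect_equal(pat$label, "rebound_bursting")
  expect_equal(pat$spikes_per_burst, 5)
  expect_equal(spikesPerBurst(pat), 5)
  # alternating burst sizes: mean over cycles
  sp2 <- c(outer(c(20, 35, 50, 65), c(0, 2000), "+"),
           outer(c(20, 35, 50, 65, 80), c(1000, 3000), "+"))
  pat2 <- classifyPattern(fakeSteady(sp2))
  expect_equal(pat2$label, "aperiodic_spiking")  # unequal per-cycle counts
  # exactly one spike per cycle is NOT rebound bursting
  pat1 <- classifyPattern(fakeSteady((0:3) * 1000 + 40))
  expect_false(pat1$label == "rebound_bursting")
  # depolarized plateau without spikes
  patDb <- classifyPattern(fakeSteady(numeric(0), v_axon = rep(-20, 101)))
  expect_equal(patDb$label, "depolarization_block")
  patNs <- classifyPattern(fakeSteady(numeric(0), v_axon = rep(-62, 101)))
  expect_equal(patNs$label, "non_spiking")
  # firing through every phase of the cycle
  spT <- as.vector(outer(seq(10, 990, by = 40), (0:3) * 1000, "+"))
  expect_equal(classifyPattern(fakeSteady(spT))$label, "tonic_spiking")
  # spikes without a settled pattern
  patU <- classifyPattern(fakeSteady(sp, settled = FALSE))
  expect_equal(patU$label, "aperiodic_spiking")
  # spikes-per-burst is only defined for bursting labels
  expect_error(spikesPerBurst(patU), "rebound")
})

test_that("burst statistics average over the analysis cycles", {
  sp <- c(outer(c(20, 35, 50, 65), c(0, 2000), "+"),
          outer(c(20, 35, 50, 65, 80), c(1000, 3000), "+"))
  b <- segmentBursts(sp, seq(0, 4000, by = 1000))
  sizes <- vapply(b, function(x) length(x[[1]]), integer(1))
  expect_equal(mean(sizes), 4.5)
})
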