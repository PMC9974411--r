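test_that("parametric drive is periodic, smooth, and correctly ordered", {
  drv <- pyloricDrive()
  dt <- 0.05
  dm <- driveMatrix(drv, dt)
  expect_equal(colnames(dm), c("AB", "PD", "PY"))
  expect_equal(nrow(dm), drv$period / dt)
  # exact periodicity on the grid: two stacked periods are identical
  expect_identical(dm, driveMatrix(drv, dt))
  # C1 smoothness across the wrap: bounded finite-difference derivative
  for (j in 1:3) {
    wrapped <- c(dm[, j], dm[1:2, j])
    d1 <- diff(wrapped) / dt
    expect_lt(max(abs(d1)), (drv$peak - drv$baseline) * pi / (2 * drv$smoothing) + 0.1)
  }
  # PD window midpoint at peak, far-outside at baseline
  mid <- round(mean(drv$windows$PD) * drv$period / dt)
  expect_equal(unname(dm[mid, "PD"]), drv$peak)
  expect_equal(unname(dm[round(0.2 * drv$period / dt), "PD"]), drv$baseline)
  # PY precedes PD/AB within the cycle; AB and PD coincide
  expect_lt(mean(drv$windows$PY), mean(drv$windows$PD))
  expect_identical(dm[, "AB"], dm[, "PD"])
  expect_error(pyloricDrive(py_window = c(0.5, 0.4)), "window")
  expect_error(pyloricDrive(py_window = c(0.40, 0.44), smoothing = 30),
               "contradictory")
})

test_that("sampled external traces are accepted and resampled", {
  tt <- seq(0, 1000, by = 10)
  tr <- cbind(tt, -60 + 20 * sin(2 * pi * tt / 1000))
  drv <- sampledDrive(1000, tr, tr, tr)
  dm <- driveMatrix(drv, 0.5)
  expect_equal(nrow(dm), 2000)
  expect_equal(unname(dm[1, "AB"]), -60)
  expect_equal(max(abs(dm[, "PD"] - (-60 + 20 * sin(2 * pi * (0:1999) * 0.5 / 1000)))),
               0, tolerance = 0.02)
  expect_error(sampledDrive(1000, tr[, 1, drop = FALSE], tr, tr), "two columns")
})

test_that("conductance sampling is uniform, bounded, and reproducible", {
  iv <- syntheticSamplingIntervals()
  pop <- sampleConductanceSets(2000, iv, seed = 8)
  expect_equal(dim(pop), c(2000, 14))
  for (nm in conductanceNames()) {
    expect_true(all(pop[[nm]] >= iv[nm, 1] & pop[[nm]] <= iv[nm, 2]))
    se <- (iv[nm, 2] - iv[nm, 1]) / sqrt(12) / sqrt(2000)
    expect_lt(abs(mean(pop[[nm]]) - mean(iv[nm, ])), 3.5 * se)
  }
  expect_identical(sampleConductanceSets(50, iv, seed = 3),
                   sampleConductanceSets(50, iv, seed = 3))
  expect_false(identical(sampleConductanceSets(50, iv, seed = 3),
                         sampleConductanceSets(50, iv, seed = 4)))
})

test_that("population bounds are the per-channel extremes", {
  parents <- fixtureParents()
  b <- conductanceBounds(parents)
  expect_equal(dim(b), c(14, 2))
  for (nm in conductanceNames()) {
    expect_equal(b[nm, "min"], min(parents[[nm]]))
    expect_equal(b[nm, "max"], max(parents[[nm]]))
    expect_true(all(parents[[nm]] >= b[nm, 1] & parents[[nm]] <= b[nm, 2]))
  }
  toy <- parents[1:3, ]
  toy$g_Na_axon <- c(1, 3, 7)
  expect_equal(unname(conductanceBounds(toy)["g_Na_axon", ]), c(1, 7))
  expect_equal(conductanceBounds(parents[sample(nrow(parents)), ]), b)
  expect_error(conductanceBounds(parents[1, ]), "degenerate")
})

test_that("parameter tables round-trip bit-exactly and validate their schema", {
  parents <- fixtureParents()[1:5, ]
  path <- withr::local_tempfile(fileext = ".csv")
  writeParameterTable(parents, path)
  back <- loadParameterTable(path)
  for (nm in conductanceNames()) expect_identical(back[[nm]], parents[[nm]])
  # missing column
  df <- read.csv(path)
  path2 <- withr::local_tempfile(fileext = ".csv")
  write.csv(df[, setdiff(names(df), "g_KCa")], path2, row.names = FALSE)
  expect_error(loadParameterTable(path2), "g_KCa")
  # unknown extra column: warning, then ignored
  df$mystery <- 1
  write.csv(df, path2, row.names = FALSE)
  expect_warning(back2 <- loadParameterTable(path2), "mystery")
  expect_false("mystery" %in% names(back2))
  # negative value names the row
  df$mystery <- NULL
  df$g_h[3] <- -0.2
  write.csv(df, path2, row.names = FALSE)
  expect_error(loadParameterTable(path2), "g_h at row 3")
  expect_error(loadParameterTable("does/not/exist.csv"), "no such file")
})

test_that("shipped fixture populations are valid and sufficiently large", {
  parents <- fixtureParents()
  elites <- fixtureElites()
  expect_gte(nrow(parents), 20)
  expect_gte(nrow(elites), 5)
  for (df in list(parents, elites)) {
    expect_true(all(conductanceNames() %in% names(df)))
    expect_true(all(as.matrix(df[, conductanceNames()]) >= 0))
    expect_equal(anyDuplicated(df$id), 0)
  }
})

test_that("bursting becomes much rarer as the sampling box widens", {
  drv <- pyloricDrive()
  wide <- screenPopulation(sampleConductanceSets(40, syntheticSamplingIntervals(3),
                                                 seed = 5), drv)
  narrow <- screenPopulation(sampleConductanceSets(40, seed = 5), drv)
  expect_lt(wide$hit_rate, narrow$hit_rate - 0.2)
  expect_gt(narrow$hit_rate, 0.5)
})

test_that("the screen keeps bursters and rejects silent candidates", {
  drv <- pyloricDrive()
  cand <- rbind(fixtureParents()[1:2, conductanceNames()],
                setNames(as.list(rep(0, 14)), conductanceNames()))
  scr <- screenPopulation(cand, drv)
  expect_equal(scr$labels[3], "non_spiking")
  expect_equal(scr$labels[1:2], rep("rebound_bursting", 2))
  expect_equal(nrow(scr$parents), 2)
  expect_equal(scr$hit_rate, 2 / 3)
  expect_true(all(!is.na(scr$spikes_per_burst[1:2])))
  expect_error(screenPopulation(cand[0, ], drv), "non-empty")
})
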