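test_that("conductance sets are validated by name and sign", {
  g <- referenceConductances()
  expect_s3_class(g, "lp_conductances")
  expect_named(conductanceSet(rev(unclass(g))), conductanceNames())
  bad <- unclass(g); bad["g_Na_axon"] <- -1
  expect_error(conductanceSet(bad), "g_Na_axon")
  expect_error(conductanceSet(unclass(g)[-1]), "g_leak_axon")
  extra <- c(unclass(g), g_bogus = 1)
  expect_error(conductanceSet(extra), "g_bogus")
})

test_that("default morphology carries the tabulated constants", {
  m <- lpMorphology()
  expect_equal(unname(m$capacitances), c(0.039, 0.8, 3.74, 5.50))
  expect_equal(unname(m$resistors), c(2.50e5, 1.80e7, 1.13e6, 2.26e7))
  expect_equal(m$axon_length, 354.5)
  expect_equal(m$axon_diam, 3.5)
  expect_error(lpMorphology(capacitances = c(0, 1, 1, 1)), "capacitances")
  cell <- buildCell(referenceConductances())
  expect_equal(cell$capacitances, c(0.039, 0.8, 3.74, 5.50))
  # chain coupling: axon -(r1+r2)- soma -(r3)- secondary -(r4)- tertiary
  expect_equal(cell$edges[, 3], c(2.50e5 + 1.80e7, 1.13e6, 2.26e7))
})

test_that("channel placement follows the compartment complements", {
  cell <- buildCell(referenceConductances())
  # axon: leak, Kd, A, Na; each neurite compartment: 7 intrinsic channels
  expect_equal(sum(cell$chanMat[, 1] == 0), 4)
  for (comp in 1:3) expect_equal(sum(cell$chanMat[, 1] == comp), 7)
  # area scaling proportional to capacitance, anchored at the soma
  g <- unclass(referenceConductances())
  somaLeak <- cell$chanMat[cell$chanMat[, 1] == 1, 3][1]
  terLeak <- cell$chanMat[cell$chanMat[, 1] == 3, 3][1]
  expect_equal(somaLeak, unname(g["g_leak"]))
  expect_equal(terLeak, unname(g["g_leak"]) * 5.50 / 0.8)
  # synapses split over secondary/tertiary by area
  syn <- cell$synMat
  expect_setequal(unique(syn[, 2]), c(2, 3))
  ab <- syn[syn[, 1] == 0, ]
  expect_equal(sum(ab[, 3]), unname(g["g_synAB"]))
  expect_equal(ab[ab[, 2] == 2, 3] / sum(ab[, 3]), 3.74 / (3.74 + 5.50))
  # registry coverage is checked
  expect_error(buildCell(referenceConductances(),
                         registry = defaultKinetics()[c("Na", "Kd")]),
               "lacks")
})

test_that("axonal Ra rescales only r2, linearly and anchored at control", {
  cell <- buildCell(referenceConductances())
  r1 <- 2.50e5
  expect_equal(setAxonalRa(cell, 100)$edges[1, 3] - r1, 1.80e7)
  expect_equal(setAxonalRa(cell, 2)$edges[1, 3] - r1, 3.60e5)
  expect_equal(setAxonalRa(cell, 500)$edges[1, 3] - r1, 9.0e7)
  # exact linearity of the anchored map
  for (ra in c(5, 37, 250)) {
    r2 <- setAxonalRa(cell, ra)$edges[1, 3] - r1
    expect_equal(setAxonalRa(cell, 2 * ra, override = TRUE)$edges[1, 3] - r1,
                 2 * r2)
  }
  # other resistors untouched
  expect_equal(setAxonalRa(cell, 2)$edges[2:3, 3], c(1.13e6, 2.26e7))
  expect_error(setAxonalRa(cell, 1), "override")
  expect_equal(setAxonalRa(cell, 1000, override = TRUE)$edges[1, 3] - r1,
               1.8e8)
})

test_that("the reference RHS conserves charge and matches closed forms", {
  drv <- function(t) c(AB = -80, PD = -80, PY = -80)
  # leak-only: dV/dt = -g (V - E) / C at several states
  cell <- passiveCell(gleak = 0.02, eleak = -60)
  st <- initState(cell, v0 = -40)
  for (v0 in c(-80, -60, -35)) {
    st[1:4] <- v0
    r <- cellRhs(cell, st, 0, drv)
    expect_equal(r$dstate[1], -0.02 * (v0 + 60) / 0.039, tolerance = 1e-10)
  }
  # all conductances zero, equal voltages: equilibrium
  g0 <- setNames(rep(0, 14), conductanceNames())
  cell0 <- buildCell(g0)
  st0 <- initState(cell0, v0 = -55)
  expect_equal(max(abs(cellRhs(cell0, st0, 0, drv)$dstate[1:4])), 0)
  # axial antisymmetry: 10 mV across a known resistor gives +/- I
  cellA <- buildCell(g0, morphology = lpMorphology(
    resistors = c(r1 = 5e6, r2 = 5e6, r3 = 1e7, r4 = 1e7)))
  stA <- initState(cellA, v0 = -60)
  stA[2] <- -50  # soma 10 mV above its neighbours
  r <- cellRhs(cellA, stA, 0, drv)
  expect_equal(sum(r$axial), 0, tolerance = 1e-12)
  expect_equal(r$axial[3], 10 / (1e7 / 1e6), tolerance = 1e-12) # 1 nA into sec
  # full model, random states: total charge drift equals total membrane
  # current (axial terms cancel pairwise)
  cell <- buildCell(referenceConductances())
  set.seed(11)
  st <- initState(cell)
  for (rep in 1:5) {
    st[1:4] <- runif(4, -80, 0)
    r <- cellRhs(cell, st, 0, function(t) c(-50, -50, -50))
    drift <- sum(cell$capacitances * r$dstate[1:4])
    expect_equal(drift, -sum(r$ionic) - sum(r$synaptic), tolerance = 1e-9)
  }
})

test_that("state layout is fixed, named, and sized consistently", {
  cell <- buildCell(referenceConductances())
  nms <- stateNames(cell)
  st <- initState(cell)
  expect_equal(length(st), length(nms))
  expect_equal(length(st), cppStateLength(cellLowLevel(cell)))
  expect_equal(nms[1:4], c("V_axon", "V_soma", "V_sec", "V_ter"))
  expect_true(all(c("m_Na_axon", "h_Na_axon", "ca_soma", "s_PD_1") %in% nms))
  # gates initialized at their steady state for -60 mV
  mNa <- st["m_Na_axon"]
  expect_equal(unname(mNa), 1 / (1 + exp(-(-60 + 32) / 5.29)), tolerance = 1e-10)
})
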