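# Shared fixtures, built in code.

# a cell whose four compartments are effectively uncoupled (terasecond
# resistors) and carry only an axonal leak: a single passive RC circuit
passiveCell <- function(gleak = 0.02, eleak = -60) {
  g <- setNames(rep(0, 14), conductanceNames())
  g["g_leak_axon"] <- gleak
  morph <- lpMorphology(resistors = c(r1 = 1e15, r2 = 1e15, r3 = 1e15,
                                      r4 = 1e15))
  buildCell(g, morphology = morph, eleak_axon = eleak, ra = 100)
}

silentDrive <- function(period = 200) {
  pyloricDrive(period = period, baseline = -80, peak = -80,
               py_window = c(0.3, 0.5), pd_window = c(0.6, 0.9),
               smoothing = 10)
}

# direct double-precision evaluation of the GHK expression, written
# independently of the compiled kernel
ghkReference <- function(pbar, w, cai, cao, v, temperature = 283.15, z = 2) {
  kOverQ <- 8.617333262e-2            # mV per K
  faraday <- 96485.33212
  xi <- z * v / (kOverQ * temperature)
  bracket <- cai * (-xi) / (expm1(-xi)) - cao * xi / expm1(xi)
  pbar * w * z * faraday * bracket
}

# synthesize an lp_steady object with prescribed spikes (for classifier tests)
fakeSteady <- function(spikes, period = 1000, cycles = 4, settled = TRUE,
                       v_axon = NULL) {
  n <- 101
  tt <- seq(0, cycles * period, length.out = n)
  if (is.null(v_axon)) v_axon <- rep(-60, n)
  V <- cbind(V_axon = v_axon, V_soma = v_axon, V_sec = v_axon,
             V_ter = v_axon)
  structure(list(settled = settled, cycles_to_settle = 2L, time = tt, V = V,
                 spikes = sort(spikes), period = period,
                 analysis_cycles = cycles, state = numeric(0), dt = 0.05),
            class = "lp_steady")
}

fixtureBounds <- function() conductanceBounds(fixtureParents())
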