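test_that("effective synapse counts follow the spine-count mapping", {
  # hand evaluation: EXN=100, EXN_IN=0.2, fac=0
  mus <- effectiveSynapseCounts(spineCounts(EXN = 100, EXN_IN = 0.2,
                                            fac = 0))
  expect_equal(mus$mu_e_NMDA, 40)
  expect_equal(mus$mu_e_AMPA, 40)
  expect_equal(mus$mu_e_GABA, 20)
  # interneuron entries: halved excitatory-share form for all receptors
  mus2 <- effectiveSynapseCounts(spineCounts(BP = 10, MP = 20, BP_IN = 0.4,
                                             MP_IN = 0.5))
  expect_equal(mus2$mu_i_NMDA, 10 * 0.6 * 0.5 + 20 * 0.5 * 0.5)
  expect_equal(mus2$mu_i_GABA, mus2$mu_i_NMDA)

  # spine loss scales every EXN-derived entry by exactly (1 - fac)
  for (f in c(0.16, 0.5, 0.9)) {
    base <- effectiveSynapseCounts(spineCounts(EXN = 37.5, EXN_IN = 0.3))
    lost <- effectiveSynapseCounts(spineCounts(EXN = 37.5, EXN_IN = 0.3,
                                               fac = f))
    expect_equal(lost$mu_e_NMDA, base$mu_e_NMDA * (1 - f))
    expect_equal(lost$mu_e_GABA, base$mu_e_GABA * (1 - f))
    expect_equal(lost$mu_i_NMDA, base$mu_i_NMDA)  # interneurons untouched
  }
  expect_error(spineCounts(EXN = -1), "EXN")
})

test_that("STP relaxes to its no-spike fixed point with the right time
           constants", {
  p <- synapseParams()
  # closed forms: u(t) = U + (u0-U) exp(-t/tau_u), x(t) = 1+(x0-1)e^(-t/tau_x)
  st <- synapseState(s_AMPA = 0.4, s_NMDA = 0.8, s_GABA = 0.2, u = 0.6,
                     x = 0.3)
  dt <- 0.5
  tt <- seq(dt, 50, by = dt)
  for (t in tt) st <- stpStep(st, FALSE, p, dt)
  tEnd <- max(tt)
  expect_equal(st$u, 0.15 + (0.6 - 0.15) * exp(-tEnd / 1500), tolerance = 1e-9)
  expect_equal(st$x, 1 + (0.3 - 1) * exp(-tEnd / 2), tolerance = 1e-9)
  expect_equal(st$s_NMDA, 0.8 * exp(-tEnd / 100), tolerance = 1e-9)
  expect_equal(st$s_AMPA, 0.4 * exp(-tEnd / 2), tolerance = 1e-9)
  # long-run fixed point (u, x, s) -> (U, 1, 0)
  for (i in 1:3000) st <- stpStep(st, FALSE, p, 10)
  expect_equal(st$u, 0.15, tolerance = 1e-6)
  expect_equal(st$x, 1, tolerance = 1e-6)
  expect_lt(st$s_NMDA, 1e-6)
})

test_that("STP spike jumps follow the ux ordering", {
  p <- synapseParams()
  st <- synapseState(u = 0.15, x = 1)
  st2 <- stpStep(st, TRUE, p, 1e-9)
  # u jump from baseline: 0.15 + 0.15*0.85 = 0.2775
  expect_equal(st2$u, 0.2775, tolerance = 1e-6)
  # s and x increments use post-jump u and pre-drop x = 1
  expect_equal(st2$s_AMPA, 1 * 0.2775 * p$gamma_AMPA, tolerance = 1e-6)
  expect_equal(st2$x, 1 - 0.2775, tolerance = 1e-6)
  # inhibitory terminal: plain gamma_I increment, no u/x involvement
  sti <- stpStep(synapseState(u = 0.4, x = 0.6), TRUE, p, 1e-9,
                 is_inhibitory = TRUE)
  expect_equal(sti$s_GABA, p$gamma_I, tolerance = 1e-6)
  expect_equal(sti$x, 0.6, tolerance = 1e-3)
})

test_that("s_NMDA stays within [0, 1] for random spike trains", {
  p <- synapseParams()
  set.seed(42)
  worst <- c(sN_lo = Inf, sN_hi = -Inf, u_lo = Inf, u_hi = -Inf,
             x_lo = Inf, x_hi = -Inf)
  for (rep in 1:100) {
    st <- synapseState()
    rate <- runif(1, 10, 400)  # Hz
    for (k in 1:300) {
      st <- stpStep(st, runif(1) < rate * 1e-3, p, dt = 1)
      worst["sN_lo"] <- min(worst["sN_lo"], st$s_NMDA)
      worst["sN_hi"] <- max(worst["sN_hi"], st$s_NMDA)
      worst["u_lo"] <- min(worst["u_lo"], st$u)
      worst["u_hi"] <- max(worst["u_hi"], st$u)
      worst["x_lo"] <- min(worst["x_lo"], st$x)
      worst["x_hi"] <- max(worst["x_hi"], st$x)
    }
  }
  expect_gte(worst[["sN_lo"]], 0)
  expect_lte(worst[["sN_hi"]], 1)
  expect_gte(worst[["u_lo"]], p$U - 1e-12)
  expect_lte(worst[["u_hi"]], 1)
  expect_gte(worst[["x_lo"]], 0)
  expect_lte(worst[["x_hi"]], 1)
})

test_that("synaptic currents vanish at V = V_L and are linear in s", {
  p <- synapseParams()
  VL <- -70
  s <- c(0.3, 0.7); w <- c(1, 2); u <- c(0.5, 0.9)
  expect_equal(nmdaCurrent(VL, s, w, u, mu = 8, p, V_L = VL), 0)
  expect_equal(ampaCurrentRec(VL, s, w, u, mu = 8, p, V_L = VL), 0)
  expect_equal(ampaCurrentExt(VL, s, p, V_L = VL), 0)
  expect_equal(gabaCurrent(VL, s, mu = 4, p, V_L = VL), 0)
  # homogeneity of degree 1 in s at fixed V
  V <- -55
  for (f in c(2, 0.5, 10)) {
    expect_equal(ampaCurrentRec(V, f * s, w, u, 8, p, VL),
                 f * ampaCurrentRec(V, s, w, u, 8, p, VL))
    expect_equal(gabaCurrent(V, f * s, 4, p, VL),
                 f * gabaCurrent(V, s, 4, p, VL))
    expect_equal(nmdaCurrent(V, f * s, w, u, 8, p, VL),
                 f * nmdaCurrent(V, s, w, u, 8, p, VL))
  }
})

test_that("single-synapse currents match hand-evaluated scalar arithmetic", {
  p <- synapseParams(g_NMDA_rec = 1.5, g_AMPA_rec = 0.4, g_GABA = 1.1,
                     gamma_mg = 0.28, beta_mg = 0.062)
  V <- -58; VL <- -70
  # NMDA: mu g (V-VL)/(1+gamma e^{-beta V}) w s u
  expected <- 8 * 1.5 * (V - VL) / (1 + 0.28 * exp(-0.062 * V)) * 2 * 0.6 * 0.9
  expect_equal(nmdaCurrent(V, s = 0.6, w = 2, u = 0.9, mu = 8, p, VL),
               expected, tolerance = 1e-12)
  expect_equal(ampaCurrentRec(V, c(0.6, 0.1), c(2, 3), c(0.9, 0.5), 8, p, VL),
               8 * 0.4 * (V - VL) * (2 * 0.6 * 0.9 + 3 * 0.1 * 0.5),
               tolerance = 1e-12)
  expect_equal(gabaCurrent(V, c(0.2, 0.3), 4, p, VL),
               4 * 1.1 * (V - VL) * 0.5, tolerance = 1e-12)
  expect_error(nmdaCurrent(V, c(0.1, 0.2), w = 1, u = 1, 8, p, VL),
               "length")
})

test_that("dendrite-to-soma transfer is bounded and saturates", {
  nl <- dendriteNonlinearity(c1 = 30, c2 = 14, c3 = -1, c4 = -50, c5 = 100,
                             c6 = 200)
  vals <- sapply(seq(-2000, 2000, by = 50), function(e)
    dendriteToSoma(e, 150, nl))
  expect_true(all(vals >= 14 - 30 - 1e-9 & vals <= 14 + 30 + 1e-9))
  expect_equal(dendriteToSoma(1e9, 100, nl), 30 + 14)
  # hand evaluation at one point
  expect_equal(dendriteToSoma(120, 40, nl),
               30 * tanh((120 - 40 - 50) / (100 * exp(-40 / 200))) + 14,
               tolerance = 1e-12)
})

test_that("total current applies the acute multipliers exactly once", {
  expect_equal(totalCurrent(0, 0, 0, 0, 0, 0), 0)
  # control identity
  expect_equal(totalCurrent(10, 5, 3, 4, 2, 1), 10 + 5 + 3 - 4 + 2 + 1)
  # forced-swim multipliers from the printed EPSC ratios
  sc <- stressScaling(beta_NMDA = 425 / 197, beta_AMPA = 98.8 / 58.6)
  expect_equal(totalCurrent(10, 0, 3, 0, 0, 0, sc),
               425 / 197 * 10 + 98.8 / 58.6 * 3, tolerance = 1e-12)
})

test_that("membrane step reproduces the analytic LIF relaxation, order 1", {
  p <- neuronParams(C_m = 200, g_L = 10, V_L = -70, V_th = 0)  # no spiking
  tau_m <- p$C_m / p$g_L
  errAt <- function(dt) {
    V <- p$V_L + 10; t <- 0
    while (t < 40 - dt / 2) {
      st <- membraneStep(V, 0, p, dt, t)
      V <- st$V; t <- t + dt
    }
    abs(V - (p$V_L + 10 * exp(-40 / tau_m)))
  }
  # fixed point
  expect_equal(membraneStep(p$V_L, 0, p, 0.05)$V, p$V_L)
  e1 <- errAt(0.4); e2 <- errAt(0.2); e3 <- errAt(0.1)
  expect_lt(e3, 0.01)
  # observed order ~1: halving dt halves the error
  expect_gt(e1 / e2, 1.6); expect_lt(e1 / e2, 2.4)
  expect_gt(e2 / e3, 1.6); expect_lt(e2 / e3, 2.4)
})

test_that("constant drive below rheobase never fires", {
  p <- neuronParams()
  rheobase <- p$g_L * (p$V_th - p$V_L)  # 200 pA
  V <- p$V_L; refr <- -Inf; spikes <- 0
  for (k in 1:20000) {
    st <- membraneStep(V, 0.98 * rheobase, p, dt = 0.05, t = k * 0.05,
                      refractory_until = refr)
    V <- st$V; refr <- st$refractory_until
    spikes <- spikes + sum(st$spiked)
  }
  expect_equal(spikes, 0)
  expect_lt(V, p$V_th)
  # and just above rheobase it does fire
  V <- p$V_L; fired <- FALSE
  for (k in 1:20000) {
    st <- membraneStep(V, 1.05 * rheobase, p, dt = 0.05, t = k * 0.05)
    V <- st$V
    if (any(st$spiked)) { fired <- TRUE; break }
  }
  expect_true(fired)
})
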