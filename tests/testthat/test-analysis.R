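test_that("capacity counting matches fixtures and the brute-force oracle", {
  proto <- stimulusProtocol()
  spec0 <- fixtureSpec(sustained = integer(0))
  spec4 <- fixtureSpec(sustained = 1:4)
  spec13 <- fixtureSpec(sustained = c(1L, 3L))
  r0 <- makeCapacityRaster(spec0, proto, seed = 1)
  r4 <- makeCapacityRaster(spec4, proto, seed = 1)
  r13 <- makeCapacityRaster(spec13, proto, seed = 1)
  expect_equal(workingMemoryCapacity(r0, attr(r0, "neurons"), proto), 0)
  expect_equal(workingMemoryCapacity(r4, attr(r4, "neurons"), proto), 4)
  expect_equal(workingMemoryCapacity(r13, attr(r13, "neurons"), proto), 2)
  # agreement with the independent per-neuron rate counter
  b <- epochBoundaries(proto)
  expect_equal(bruteForceCapacity(r13, attr(r13, "neurons"),
                                  b[["cue"]] - 200, b[["cue"]]), 2)
  expect_error(workingMemoryCapacity(
    r0, data.frame(neuron = 1, group = 1, is_exc = FALSE), proto),
    "excitatory")
})

test_that("capacity is monotone under criterion relaxation", {
  proto <- stimulusProtocol()
  spec <- fixtureSpec(sustained = c(2L, 4L), rate_active = 14,
                      rate_silent = 6)
  r <- makeCapacityRaster(spec, proto, seed = 3)
  nt <- attr(r, "neurons")
  caps <- sapply(c(30, 20, 12, 8, 4, 1), function(th)
    workingMemoryCapacity(r, nt, proto,
                          capacityCriterion(rate_threshold = th)))
  expect_true(all(diff(caps) >= 0))
})

test_that("spike-count matrix bins exactly and conserves events", {
  r <- data.frame(time_ms = 75, neuron = 1L)
  m <- spikeCountMatrix(r, neurons = 1L, bin = 50, span = 200)
  expect_equal(as.integer(m), c(0L, 1L, 0L, 0L))
  set.seed(8)
  rr <- data.frame(time_ms = runif(500, 0, 1000),
                   neuron = sample(1:5, 500, replace = TRUE))
  mm <- spikeCountMatrix(rr, 1:5, bin = 50, span = 1000)
  expect_equal(sum(mm), 500)
  # independent histogram oracle per neuron
  for (id in 1:5) {
    h <- hist(rr$time_ms[rr$neuron == id], breaks = seq(0, 1000, 50),
              plot = FALSE)$counts
    expect_equal(as.integer(mm[as.character(id), ]), h)
  }
  expect_error(spikeCountMatrix(r, 1L, bin = 30, span = 100), "divide")
})

test_that("timescale fit recovers a noiseless exponential to 1e-6", {
  for (tau0 in c(80, 200, 500)) {
    lags <- (1:20) * 50
    fit <- fitTimescale(lags, exp(-lags / tau0), bin = 50)
    expect_true(fit$converged)
    expect_equal(fit$tau, tau0, tolerance = 1e-6)
    expect_equal(fit$a, 1, tolerance = 1e-4)
    expect_equal(fit$b, 0, tolerance = 1e-4)
  }
})

test_that("timescale estimator recovers the latent AR(1) timescale", {
  ratios <- sapply(1:5, function(s) {
    counts <- makeAr1Counts(200, span = 5000, bin = 50, seed = s)
    fit <- autocorrelationTimescale(counts, max_lag_windows = 20)
    fit$tau / 200
  })
  expect_lt(abs(median(ratios) - 1), 0.25)
})

test_that("white-noise counts yield a sub-bin or non-converged timescale", {
  set.seed(99)
  counts <- matrix(rpois(30 * 100, 1.5), 30, 100)
  attr(counts, "bin_ms") <- 50
  fit <- autocorrelationTimescale(counts)
  expect_true(!fit$converged || fit$tau < 50)
})

test_that("timescale estimation tolerates silent units and zero variance", {
  counts <- makeAr1Counts(150, span = 5000, bin = 50, seed = 2)
  withEmpty <- rbind(counts, matrix(0L, 5, ncol(counts)))
  attr(withEmpty, "bin_ms") <- 50
  a <- autocorrelationTimescale(counts)
  b <- autocorrelationTimescale(withEmpty)
  # silent units are dropped, so the estimate is unchanged
  expect_equal(a$tau, b$tau, tolerance = 1e-12)
  # permuting unit labels changes nothing (pool averages over units)
  perm <- counts[sample(nrow(counts)), ]
  attr(perm, "bin_ms") <- 50
  expect_equal(autocorrelationTimescale(perm)$tau, a$tau,
               tolerance = 1e-12)
  allZero <- matrix(0L, 4, 100); attr(allZero, "bin_ms") <- 50
  z <- autocorrelationTimescale(allZero)
  expect_false(z$converged)
  expect_true(is.na(z$tau))
})

# Build a SimulationResult whose raster has a known latent timescale per
# epoch segment: doubly-stochastic Poisson spikes, log-AR(1) rate.
syntheticResult <- function(tau_by_seg, proto, n_units = 40, seed = 1,
                            mean_rate = 25) {
  set.seed(seed)
  b <- epochBoundaries(proto)
  segs <- data.frame(start = b[-length(b)], end = b[-1],
                     tau = tau_by_seg)
  tt <- list(); id <- list(); k <- 0
  dtb <- 10  # ms resolution of the latent rate
  for (i in seq_len(n_units)) {
    for (s in seq_len(nrow(segs))) {
      nW <- floor((segs$end[s] - segs$start[s]) / dtb)
      if (nW < 1) next
      phi <- exp(-dtb / segs$tau[s])
      z <- numeric(nW); z[1] <- rnorm(1)
      for (w in 2:max(2, nW))
        if (w <= nW) z[w] <- phi * z[w - 1] + rnorm(1, sd = sqrt(1 - phi^2))
      rate <- exp(log(mean_rate) - 0.125 + 0.5 * z)
      cnt <- rpois(nW, rate * dtb / 1000)
      wi <- which(cnt > 0)
      if (!length(wi)) next
      k <- k + 1
      tt[[k]] <- segs$start[s] + rep(wi - 1, cnt[wi]) * dtb +
        runif(sum(cnt), 0, dtb)
      id[[k]] <- rep(i, sum(cnt))
    }
  }
  raster <- data.frame(time_ms = unlist(tt), neuron = unlist(id))
  groupOf <- rep(1L, n_units)
  isExc <- rep(c(TRUE, FALSE), length.out = n_units)
  methods::new("SimulationResult", raster = raster,
               currents = data.frame(time_ms = numeric(0),
                                     population = character(0),
                                     receptor = character(0),
                                     value = numeric(0)),
               neuronCurrents = NULL, protocol = proto,
               condition = "control", groupOf = groupOf, isExc = isExc,
               dt = 0.1, span = protocolSpan(proto), seed = 1L,
               configHash = "synthetic")
}

test_that("epoch-anchored timescales separate fast and slow regimes", {
  proto <- stimulusProtocol(t_fixation = 0, t_memory = 1400, t_delay = 0,
                            t_cue = 0, t_post = 3000)
  # memory-epoch latent tau 40 ms; post-cue latent tau 400 ms
  res <- syntheticResult(tau_by_seg = c(40, 40, 40, 40, 400), proto,
                         seed = 7)
  ts <- epochTimescales(res, epochs = c("memory", "cue"), bin = 50)
  expect_true(ts$memory$E$converged && ts$cue$E$converged)
  expect_gt(ts$cue$E$tau, ts$memory$E$tau)
  # identical E and I sub-rasters give identical fits
  res2 <- res
  res2@isExc <- rep(TRUE, length(res2@isExc))
  res3 <- res
  res3@isExc <- rep(FALSE, length(res3@isExc))
  tE <- epochTimescales(res2, epochs = "cue", bin = 50)$cue$E
  tI <- epochTimescales(res3, epochs = "cue", bin = 50)$cue$I
  expect_equal(tE$tau, tI$tau)
})

test_that("stationary rasters give matching memory and cue timescales", {
  proto <- stimulusProtocol(t_fixation = 0, t_memory = 1400, t_delay = 0,
                            t_cue = 0, t_post = 3600)
  res <- syntheticResult(tau_by_seg = rep(200, 5), proto, seed = 11,
                         n_units = 60)
  ts <- epochTimescales(res, epochs = c("memory", "cue"), bin = 50)
  expect_true(ts$memory$E$converged && ts$cue$E$converged)
  expect_gt(ts$cue$E$tau / ts$memory$E$tau, 0.4)
  expect_lt(ts$cue$E$tau / ts$memory$E$tau, 2.5)
})

test_that("sweep correlation matches the textbook Pearson formula", {
  tab <- data.frame(axis = 1:6, capacity = c(0, 1, 1, 2, 3, 4))
  r1 <- sweepCorrelation(tab, "axis")
  expect_equal(r1$r, cor(1:6, tab$capacity), tolerance = 1e-12)
  lin <- data.frame(axis = 1:5, capacity = 2 * (1:5) + 3)
  expect_equal(sweepCorrelation(lin, "axis")$r, 1, tolerance = 1e-12)
  neg <- data.frame(axis = 1:5, capacity = -(1:5))
  expect_equal(sweepCorrelation(neg, "axis")$r, -1, tolerance = 1e-12)
  # textbook formula on random pairs
  set.seed(2); x <- rnorm(40); y <- rnorm(40)
  man <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(sweepCorrelation(data.frame(axis = x, capacity = y),
                                "axis")$r, man, tolerance = 1e-12)
  const <- data.frame(axis = 1:5, capacity = rep(2, 5))
  expect_true(is.na(sweepCorrelation(const, "axis")$r))
})

test_that("mean current traces average per-neuron records correctly", {
  proto <- tinyProtocol()
  tms <- seq(0, 100, by = 10)
  f <- sin(tms / 10)
  nc <- list(NMDA = cbind(f, -f, 2 * f),
             AMPA_rec = cbind(f, f, f))
  attr(nc, "time_ms") <- tms
  res <- methods::new("SimulationResult",
                      raster = data.frame(time_ms = numeric(0),
                                          neuron = integer(0)),
                      currents = data.frame(time_ms = numeric(0),
                                            population = character(0),
                                            receptor = character(0),
                                            value = numeric(0)),
                      neuronCurrents = nc, protocol = proto,
                      condition = "control", groupOf = c(1L, 1L, 2L),
                      isExc = c(TRUE, TRUE, FALSE), dt = 0.1,
                      span = protocolSpan(proto), seed = 1L,
                      configHash = "x")
  # two E neurons with traces f and -f average to zero
  expect_equal(meanCurrentTraces(res, "E", "NMDA")$value, rep(0,
                                                              length(tms)))
  # single-neuron population returns its own trace
  expect_equal(meanCurrentTraces(res, "I", "NMDA")$value, 2 * f)
  expect_error(meanCurrentTraces(res, "I", "GABA"), "not recorded")
})
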