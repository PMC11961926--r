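test_that("quiescent network produces no spikes and zero synaptic traces", {
  cfg <- tinyNetworkConfig(I_bg = 0)
  net <- buildNetwork(cfg, seed = 1)
  proto <- tinyProtocol(rate_memory = 0, rate_cue = 0, rate_background = 0)
  res <- runSimulation(net, proto, dt = 0.1, seed = 1)
  expect_equal(nrow(spikeRaster(res)), 0)
  expect_true(all(currentTraces(res)$value == 0))
})

test_that("simulation is deterministic per seed", {
  net <- buildNetwork(tinyNetworkConfig(), seed = 1)
  proto <- tinyProtocol()
  a <- runSimulation(net, proto, dt = 0.1, seed = 5)
  b <- runSimulation(net, proto, dt = 0.1, seed = 5)
  c <- runSimulation(net, proto, dt = 0.1, seed = 6)
  expect_identical(spikeRaster(a), spikeRaster(b))
  expect_identical(currentTraces(a), currentTraces(b))
  expect_false(identical(spikeRaster(a), spikeRaster(c)))
  expect_identical(a@configHash, c@configHash)
})

test_that("recording stride is passive: doubling it changes no spike
           times", {
  net <- buildNetwork(tinyNetworkConfig(), seed = 2)
  proto <- tinyProtocol()
  a <- runSimulation(net, proto, dt = 0.1, seed = 3, record_stride = 1)
  b <- runSimulation(net, proto, dt = 0.1, seed = 3, record_stride = 2)
  expect_identical(spikeRaster(a), spikeRaster(b))
  expect_equal(nrow(currentTraces(b)), nrow(currentTraces(a)) / 2,
               tolerance = 0.01)
})

test_that("isolated neurons under constant drive spike at the closed-form
           LIF period", {
  pc <- as.list(setNames(rep(0, 8), names(networkConfig()$p_connect)))
  cfg <- networkConfig(n_groups = 4, n_exc_per_group = 2,
                       n_inh_per_group = 1, p_connect = pc, I_bg = 320)
  net <- buildNetwork(cfg, seed = 6)
  proto <- stimulusProtocol(t_fixation = 1000, t_memory = 0, t_delay = 0,
                            t_cue = 0, t_post = 0, rate_memory = 0,
                            rate_cue = 0)
  dt <- 0.02
  res <- runSimulation(net, proto, dt = dt, seed = 1)
  r <- spikeRaster(res)
  nl <- do.call(dendriteNonlinearity, net@nonlinearity)
  for (i in seq_along(net@groupOf)) {
    p <- net@neurons[i, ]
    I_sd <- nl$c1 * tanh((cfg$I_bg + nl$c4) / nl$c5) + nl$c2
    I <- cfg$I_bg + I_sd
    drive <- p$V_L + I / p$g_L
    if (drive <= p$V_th) next
    tau_m <- p$C_m / p$g_L
    isi_expected <- p$t_ref +
      tau_m * log((drive - p$V_reset) / (drive - p$V_th))
    isis <- diff(r$time_ms[r$neuron == i])
    expect_gt(length(isis), 3)
    expect_lt(abs(median(isis) - isi_expected),
              max(0.2, 0.03 * isi_expected))
  }
})

test_that("numerical blow-up is reported with step context", {
  net <- buildNetwork(tinyNetworkConfig(), seed = 1)
  net@neurons$V_L[3] <- NaN  # corrupted state must be caught, not simulated
  expect_error(runSimulation(net, tinyProtocol(), dt = 0.5, seed = 1),
               "blow-up.*neuron 3")
})

test_that("sweep tables enumerate grid x replicate with seed isolation", {
  net <- buildNetwork(tinyNetworkConfig(), seed = 1)
  proto <- tinyProtocol()
  tab <- runSweep(net, proto, sweepGrid(gamma_AMPA = 1, replicates = 2),
                  dt = 0.2, verbose = FALSE)
  expect_equal(nrow(tab), 2)
  expect_equal(tab$gamma_AMPA, c(1, 1))
  expect_false(any(duplicated(tab$seed)))
  tab2 <- runSweep(net, proto,
                   sweepGrid(gamma_AMPA = c(0.5, 2), replicates = 1),
                   dt = 0.2, verbose = FALSE)
  expect_equal(sort(tab2$gamma_AMPA), c(0.5, 2))
  expect_true(all(is.na(tab2$error)))
  expect_true(is.numeric(tab2$capacity))
})

test_that("sweep output file supports resuming", {
  net <- buildNetwork(tinyNetworkConfig(), seed = 1)
  proto <- tinyProtocol()
  out <- file.path(tempdir(), "sweep_resume.tsv")
  unlink(out)
  grid <- sweepGrid(gamma_AMPA = c(1, 2), replicates = 1)
  full <- runSweep(net, proto, grid, dt = 0.2, out_tsv = out,
                   verbose = FALSE)
  # resume with the file already complete: must not rerun anything
  again <- runSweep(net, proto, grid, dt = 0.2, out_tsv = out,
                    verbose = FALSE)
  expect_equal(again$capacity, full$capacity)
  unlink(out)
})

test_that("raster and trace files round-trip", {
  net <- buildNetwork(tinyNetworkConfig(), seed = 3)
  proto <- tinyProtocol()
  res <- runSimulation(net, proto, dt = 0.1, seed = 4)
  f <- file.path(tempdir(), "raster.txt")
  writeRaster(spikeRaster(res), f, meta = list(span_ms = res@span),
              neurons = neuronTable(res))
  back <- readRaster(f)
  expect_equal(back$time_ms, spikeRaster(res)$time_ms)
  expect_equal(back$neuron, spikeRaster(res)$neuron)
  expect_equal(attr(back, "meta")$span_ms, res@span)
  expect_equal(attr(back, "neurons"), neuronTable(res))
  f2 <- file.path(tempdir(), "traces.tsv")
  writeTraces(currentTraces(res), f2)
  tr <- readTraces(f2)
  expect_equal(tr$value, currentTraces(res)$value)
  expect_equal(tr$time_ms, currentTraces(res)$time_ms)
})
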