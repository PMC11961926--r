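# Shared builders for desk-scale test objects.

tinyNetworkConfig <- function(...) {
  networkConfig(n_groups = 4, n_exc_per_group = 6, n_inh_per_group = 2, ...)
}

tinyProtocol <- function(...) {
  stimulusProtocol(t_fixation = 100, t_memory = 100, t_delay = 200,
                   t_cue = 5, t_post = 95, ...)
}

# Independent brute-force capacity oracle: loops over neurons and counts
# per-neuron rates directly; shares no code with workingMemoryCapacity.
bruteForceCapacity <- function(raster, neurons, w0, w1, rate_threshold = 10,
                               fraction_active = 0.5) {
  dur_s <- (w1 - w0) / 1000
  nGroups <- length(unique(neurons$group))
  capacity <- 0L
  for (g in sort(unique(neurons$group))) {
    ids <- neurons$neuron[neurons$group == g & neurons$is_exc]
    nActive <- 0L
    for (id in ids) {
      k <- 0L
      for (tt in raster$time_ms[raster$neuron == id])
        if (tt >= w0 && tt < w1) k <- k + 1L
      if (k / dur_s >= rate_threshold) nActive <- nActive + 1L
    }
    if (nActive / length(ids) >= fraction_active) capacity <- capacity + 1L
  }
  capacity
}
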