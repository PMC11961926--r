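#' @include AllClasses.R protocol.R analysis.R
NULL

#' Specification for synthetic analysis fixtures
#'
#' Describes a raster fixture: group structure, which groups sustain firing
#' through the delay, and the firing rates per phase. Used to test the
#' measurement layer without running the simulator.
#'
#' @param n_groups Number of selective groups.
#' @param n_exc_per_group,n_inh_per_group Neurons per group by type.
#' @param sustained Integer ids of the groups that keep firing through the
#'   delay (subset of \code{1:n_groups}).
#' @param rate_active Delay-period rate (Hz) of sustained groups.
#' @param rate_silent Delay-period rate (Hz) of non-sustained groups.
#' @param rate_baseline Fixation-period rate (Hz) of everyone.
#' @param rate_memory Memory-period rate (Hz) of everyone (all groups are
#'   driven during the stimulus).
#' @return A validated list of class \code{"FixtureSpec"}.
#' @export
fixtureSpec <- function(n_groups = 4, n_exc_per_group = 40,
                        n_inh_per_group = 10, sustained = integer(0),
                        rate_active = 40, rate_silent = 1,
                        rate_baseline = 1, rate_memory = 30) {
  assertScalar(n_groups, "n_groups", positive = TRUE)
  sustained <- as.integer(sustained)
  if (length(sustained) && !all(sustained %in% seq_len(n_groups)))
    stop("sustained must be a subset of the groups", call. = FALSE)
  for (nm in c("rate_active", "rate_silent", "rate_baseline", "rate_memory"))
    assertScalar(get(nm), nm, nonneg = TRUE)
  structure(list(n_groups = as.integer(n_groups),
                 n_exc_per_group = as.integer(n_exc_per_group),
                 n_inh_per_group = as.integer(n_inh_per_group),
                 sustained = sustained, rate_active = rate_active,
                 rate_silent = rate_silent, rate_baseline = rate_baseline,
                 rate_memory = rate_memory),
            class = "FixtureSpec")
}

#' Synthetic raster with a chosen number of sustained groups
#'
#' Generates an independent-Poisson raster over the protocol span in which
#' the sustained groups fire at \code{rate_active} through memory, delay,
#' cue and post epochs while the remaining groups fall back to
#' \code{rate_silent} after the memory epoch. Inhibitory neurons in
#' sustained groups follow the excitatory rate (inhibitory co-activation);
#' elsewhere they stay at baseline. Deterministic per seed.
#'
#' @param spec A \code{\link{fixtureSpec}}.
#' @param proto A \code{\linkS4class{StimulusProtocol}}.
#' @param seed Integer seed.
#' @return data.frame (\code{time_ms}, \code{neuron}) with a
#'   \code{neurons} attribute holding the group/type table.
#' @export
makeCapacityRaster <- function(spec, proto = stimulusProtocol(), seed = 1) {
  stopifnot(inherits(spec, "FixtureSpec"), is(proto, "StimulusProtocol"))
  gsz <- spec$n_exc_per_group + spec$n_inh_per_group
  n <- spec$n_groups * gsz
  groupOf <- rep(seq_len(spec$n_groups), each = gsz)
  isExc <- rep(c(rep(TRUE, spec$n_exc_per_group),
                 rep(FALSE, spec$n_inh_per_group)), spec$n_groups)
  b <- epochBoundaries(proto)
  segs <- data.frame(start = b[-length(b)], end = b[-1],
                     epoch = c("fixation", "memory", "delay", "cue", "post"))
  withStream(seed, "fixtures", {
    tt <- list(); id <- list(); k <- 0L
    for (i in seq_len(n)) {
      sust <- groupOf[i] %in% spec$sustained
      for (s in seq_len(nrow(segs))) {
        r <- switch(segs$epoch[s],
                    fixation = spec$rate_baseline,
                    memory = spec$rate_memory,
                    if (sust) spec$rate_active else spec$rate_silent)
        dur <- segs$end[s] - segs$start[s]
        if (r <= 0 || dur <= 0) next
        m <- rpois(1, r * dur / 1000)
        if (m == 0) next
        k <- k + 1L
        tt[[k]] <- runif(m, segs$start[s], segs$end[s])
        id[[k]] <- rep(i, m)
      }
    }
    raster <- if (k > 0) {
      df <- data.frame(time_ms = unlist(tt), neuron = unlist(id))
      df[order(df$time_ms), , drop = FALSE]
    } else data.frame(time_ms = numeric(0), neuron = integer(0))
    rownames(raster) <- NULL
    attr(raster, "neurons") <- data.frame(neuron = seq_len(n),
                                          group = groupOf, is_exc = isExc)
    raster
  })
}

#' Doubly-stochastic Poisson counts with a known latent timescale
#'
#' Each unit carries an independent latent AR(1) process on the log rate
#' (keeping rates positive) with autocorrelation \eqn{e^{-\Delta/\tau}};
#' counts per window are Poisson with that rate. Because the Poisson
#' sampling only attenuates the count autocorrelation by a lag-independent
#' factor, the latent decay constant is recoverable from the counts.
#'
#' @param tau_latent Latent timescale (ms), > 0.
#' @param span Total length (ms).
#' @param bin Window length (ms).
#' @param seed Integer seed.
#' @param n_units Number of independent units.
#' @param mean_rate Mean firing rate (Hz).
#' @param sd_log Standard deviation of the latent log-rate fluctuation.
#' @return Integer matrix (units x windows) with attribute \code{bin_ms},
#'   ready for \code{\link{autocorrelationTimescale}}.
#' @export
makeAr1Counts <- function(tau_latent, span = 5000, bin = 50, seed = 1,
                          n_units = 30, mean_rate = 20, sd_log = 0.5) {
  assertScalar(tau_latent, "tau_latent", positive = TRUE)
  assertScalar(span, "span", positive = TRUE)
  assertScalar(bin, "bin", positive = TRUE)
  nW <- as.integer(floor(span / bin))
  phi <- exp(-bin / tau_latent)
  withStream(seed, "fixtures", {
    m <- matrix(0L, n_units, nW)
    for (i in seq_len(n_units)) {
      z <- numeric(nW)
      z[1] <- rnorm(1)
      innov <- rnorm(nW - 1, sd = sqrt(1 - phi^2))
      for (w in 2:nW) z[w] <- phi * z[w - 1] + innov[w - 1]
      # log-rate with mean corrected so E[rate] = mean_rate
      rate <- exp(log(mean_rate) - sd_log^2 / 2 + sd_log * z)
      m[i, ] <- rpois(nW, rate * bin / 1000)
    }
    attr(m, "bin_ms") <- bin
    m
  })
}
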