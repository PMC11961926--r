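#' @include AllClasses.R
NULL

#' Construct a short-term recall protocol
#'
#' The default paradigm: a 1000 ms fixation period, a 400 ms memory stimulus,
#' a 1000 ms delay, a 5 ms cue probe, then a post-cue observation period.
#' Stimulus intensity is carried by the Poisson rate of the aggregate
#' external drive each excitatory neuron receives; the cue uses the memory
#' intensity by default (same intensity, different duration). An optional
#' linear ramp multiplies the memory-epoch rate from \code{ramp_start} to 1
#' across the epoch (default: constant, no ramp).
#'
#' @param t_fixation,t_memory,t_delay,t_cue,t_post Epoch durations (ms).
#' @param rate_memory Poisson rate (Hz) of the memory stimulus.
#' @param rate_cue Poisson rate (Hz) of the cue; defaults to
#'   \code{rate_memory}.
#' @param rate_background Poisson rate (Hz) outside stimulus epochs.
#' @param ramp_start Relative rate at memory-epoch onset (1 = constant).
#' @return A \code{\linkS4class{StimulusProtocol}}.
#' @export
stimulusProtocol <- function(t_fixation = 1000, t_memory = 400,
                             t_delay = 1000, t_cue = 5, t_post = 500,
                             rate_memory = 900, rate_cue = rate_memory,
                             rate_background = 0, ramp_start = 1) {
  assertFraction(ramp_start, "ramp_start")
  p <- methods::new("StimulusProtocol", t_fixation = t_fixation,
                    t_memory = t_memory, t_delay = t_delay, t_cue = t_cue,
                    t_post = t_post, rate_memory = rate_memory,
                    rate_cue = rate_cue, rate_background = rate_background)
  attr(p, "ramp_start") <- ramp_start
  p
}

#' Epoch boundaries of a protocol
#'
#' @param proto A \code{\linkS4class{StimulusProtocol}}.
#' @return Named numeric vector of epoch start times (ms): fixation, memory,
#'   delay, cue, post, end.
#' @export
epochBoundaries <- function(proto) {
  stopifnot(is(proto, "StimulusProtocol"))
  b <- cumsum(c(fixation = 0, memory = proto@t_fixation,
                delay = proto@t_memory, cue = proto@t_delay,
                post = proto@t_cue, end = proto@t_post))
  names(b) <- c("fixation", "memory", "delay", "cue", "post", "end")
  b
}

#' Map a time to its protocol epoch
#'
#' Epochs are half-open intervals [start, end); times at or beyond the end
#' of the cue fall in "post".
#'
#' @param t Time (ms), scalar or vector, >= 0.
#' @param proto A \code{\linkS4class{StimulusProtocol}}.
#' @return Character vector of epoch labels.
#' @examples
#' epochOf(c(0, 1000, 1399.9, 1400, 2400, 2405), stimulusProtocol())
#' @export
epochOf <- function(t, proto) {
  if (any(t < 0)) stop("t must be >= 0", call. = FALSE)
  b <- epochBoundaries(proto)
  labs <- c("fixation", "memory", "delay", "cue", "post")
  idx <- findInterval(t, b[-1]) + 1L
  labs[pmin(idx, 5L)]
}

# Per-time external rate (Hz), vectorized; carries the optional memory ramp.
protocolRate <- function(t, proto) {
  ep <- epochOf(t, proto)
  r <- ifelse(ep == "memory", proto@rate_memory,
              ifelse(ep == "cue", proto@rate_cue, proto@rate_background))
  ramp <- attr(proto, "ramp_start") %||% 1
  if (ramp < 1) {
    b <- epochBoundaries(proto)
    inMem <- ep == "memory"
    frac <- (t[inMem] - b[["memory"]]) / max(proto@t_memory, 1e-9)
    r[inMem] <- r[inMem] * (ramp + (1 - ramp) * frac)
  }
  r
}

#' Generate external Poisson input spike trains
#'
#' Independent homogeneous Poisson trains per target neuron, with the rate
#' switching by epoch (and optionally ramping across the memory epoch).
#' Deterministic for a given seed (inputs stream).
#'
#' @param proto A \code{\linkS4class{StimulusProtocol}}.
#' @param n_targets Number of target neurons.
#' @param seed Integer seed.
#' @return Object of class \code{"InputSpikes"}: a list of sorted spike-time
#'   vectors (ms), one per target.
#' @export
generatePoissonInput <- function(proto, n_targets, seed) {
  stopifnot(is(proto, "StimulusProtocol"))
  b <- epochBoundaries(proto)
  span <- b[["end"]]
  withStream(seed, "inputs", {
    out <- vector("list", n_targets)
    epochs <- data.frame(start = b[-length(b)], end = b[-1])
    rates <- c(proto@rate_background, proto@rate_memory,
               proto@rate_background, proto@rate_cue,
               proto@rate_background)
    for (i in seq_len(n_targets)) {
      tt <- numeric(0)
      for (k in seq_len(nrow(epochs))) {
        dur <- epochs$end[k] - epochs$start[k]
        if (dur <= 0 || rates[k] <= 0) next
        # thinning against the ramp keeps the inhomogeneous case exact
        nmax <- rpois(1, rates[k] * dur / 1000)
        if (nmax == 0) next
        cand <- sort(runif(nmax, epochs$start[k], epochs$end[k]))
        keep <- runif(nmax) <= protocolRate(cand, proto) / rates[k]
        tt <- c(tt, cand[keep])
      }
      out[[i]] <- tt
    }
    structure(out, class = "InputSpikes", span = span)
  })
}
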