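#' @include params.R
NULL

#' One short-term-plasticity / gating step for a presynaptic terminal
#'
#' Advances the synaptic state of one presynaptic neuron by \code{dt}.
#' Between spikes the gating fractions decay exponentially with their
#' receptor time constants, utilization \code{u} relaxes to the baseline
#' \code{U} with \code{tau_u} and resources \code{x} recover to 1 with
#' \code{tau_x}; the decay uses the exact exponential update, which is
#' unconditionally stable and coincides with Euler in the small-\code{dt}
#' limit. On a spike the jumps are applied in the "ux" order: first
#' \code{u <- u + U(1-u)}, then the gating and resource increments use the
#' post-jump \code{u} and pre-drop \code{x}:
#' \code{s_AMPA <- s_AMPA + x u gamma_AMPA},
#' \code{s_NMDA <- s_NMDA + x u (1 - s_NMDA) gamma_NMDA},
#' \code{x <- x - u x}. Inhibitory terminals instead increment
#' \code{s_GABA <- s_GABA + gamma_I}, with no utilization/resource
#' dependence. No clamping is applied anywhere; the invariants
#' \code{U <= u <= 1}, \code{0 <= x <= 1} hold by construction, and
#' \code{s_NMDA <= 1} holds whenever \code{gamma_NMDA <= 1}.
#'
#' @param state A \code{\link{synapseState}}.
#' @param spiked Logical; did this presynaptic neuron spike this step?
#' @param p A \code{\link{synapseParams}}.
#' @param dt Time step (ms), > 0.
#' @param is_inhibitory Logical; inhibitory terminals drive GABA gating only.
#' @return The advanced \code{SynapseState}.
#' @examples
#' st <- synapseState(u = 0.15)
#' stpStep(st, spiked = TRUE, synapseParams(), dt = 0.05)$u  # 0.2775
#' @export
stpStep <- function(state, spiked, p, dt, is_inhibitory = FALSE) {
  stopifnot(inherits(state, "SynapseState"), inherits(p, "SynapseParams"))
  assertScalar(dt, "dt", positive = TRUE)
  s <- state
  s$s_AMPA <- s$s_AMPA * exp(-dt / p$tau_AMPA)
  s$s_NMDA <- s$s_NMDA * exp(-dt / p$tau_NMDA)
  s$s_GABA <- s$s_GABA * exp(-dt / p$tau_GABA)
  s$u <- p$U + (s$u - p$U) * exp(-dt / p$tau_u)
  s$x <- 1 + (s$x - 1) * exp(-dt / p$tau_x)
  if (isTRUE(spiked)) {
    if (is_inhibitory) {
      s$s_GABA <- s$s_GABA + p$gamma_I
    } else {
      u2 <- s$u + p$U * (1 - s$u)
      inc <- s$x * u2
      s$s_AMPA <- s$s_AMPA + inc * p$gamma_AMPA
      s$s_NMDA <- s$s_NMDA + inc * (1 - s$s_NMDA) * p$gamma_NMDA
      s$x <- s$x - inc
      s$u <- u2
    }
  }
  s
}

#' Recurrent NMDA current
#'
#' \eqn{I_{NMDA} = \beta_{NMDA}\,\mu\, g\, (V - V_L) /
#' (1 + \gamma e^{-\beta V}) \sum_j w_j s_j u_j}. The magnesium-block factor
#' uses the voltage-dependence constants \code{gamma_mg}, \code{beta_mg} from
#' \code{p}. Returns a magnitude that vanishes at \code{V = V_L}; the signed
#' combination into the membrane equation happens in
#' \code{\link{totalCurrent}}.
#'
#' @param V Postsynaptic membrane potential (mV), scalar or vector.
#' @param s NMDA gating fractions of the presynaptic terminals.
#' @param w Synaptic weights, same length as \code{s}.
#' @param u Utilization values, same length as \code{s}.
#' @param mu Effective synapse-count multiplier of the postsynaptic neuron.
#' @param p \code{\link{synapseParams}} supplying \code{g_NMDA_rec},
#'   \code{gamma_mg}, \code{beta_mg} and \code{V_L} via \code{V_L} argument.
#' @param V_L Driving-force reference potential (mV).
#' @param beta_NMDA Acute-stress multiplier (default 1; the engine applies
#'   acute factors once, in \code{\link{totalCurrent}}).
#' @return Current (pA), same length as \code{V}.
#' @export
nmdaCurrent <- function(V, s, w, u, mu, p, V_L = -70, beta_NMDA = 1) {
  if (length(s) != length(w) || length(s) != length(u))
    stop("s, w, u must have the same length", call. = FALSE)
  drive <- sum(w * s * u)
  beta_NMDA * mu * p$g_NMDA_rec * (V - V_L) /
    (1 + p$gamma_mg * exp(-p$beta_mg * V)) * drive
}

#' External AMPA current
#'
#' \eqn{I_{AMPA,ext} = g_{AMPA,ext} (V - V_L) \sum_j s_j}; the external drive
#' carries no recurrent weights or short-term plasticity.
#'
#' @inheritParams nmdaCurrent
#' @param s_ext External AMPA gating fractions.
#' @return Current (pA).
#' @export
ampaCurrentExt <- function(V, s_ext, p, V_L = -70) {
  p$g_AMPA_ext * (V - V_L) * sum(s_ext)
}

#' Recurrent AMPA current
#'
#' \eqn{I_{AMPA,rec} = \beta_{AMPA}\,\mu\, g\, (V - V_L) \sum_j w_j s_j u_j}.
#'
#' @inheritParams nmdaCurrent
#' @param beta_AMPA Acute-stress multiplier (default 1).
#' @return Current (pA).
#' @export
ampaCurrentRec <- function(V, s, w, u, mu, p, V_L = -70, beta_AMPA = 1) {
  if (length(s) != length(w) || length(s) != length(u))
    stop("s, w, u must have the same length", call. = FALSE)
  beta_AMPA * mu * p$g_AMPA_rec * (V - V_L) * sum(w * s * u)
}

#' GABA current
#'
#' \eqn{I_{GABA} = \mu\, g_{GABA} (V - V_L) \sum_j s_j}. As defined, the
#' inhibitory sum carries no per-synapse weight term; the current is linear
#' in \code{s}, so callers that weight their inhibitory inputs can fold the
#' weights into the gating vector.
#'
#' @inheritParams nmdaCurrent
#' @param s GABA gating fractions of the connected inhibitory terminals.
#' @return Current (pA); a magnitude, subtracted from the excitatory drive by
#'   \code{\link{totalCurrent}}.
#' @export
gabaCurrent <- function(V, s, mu, p, V_L = -70) {
  mu * p$g_GABA * (V - V_L) * sum(s)
}

#' Dendrite-to-soma current transfer
#'
#' The saturating two-compartment transfer
#' \eqn{I_{soma} = c_1 \tanh((I_{exc} + c_3 I_{inh} + c_4)/
#' (c_5 e^{-I_{inh}/c_6})) + c_2}, where \eqn{I_{exc}} is the total
#' excitatory dendritic current (NMDA + external AMPA + recurrent AMPA +
#' background) and \eqn{I_{inh}} the dendritic GABA current. Output is
#' bounded in \eqn{[c_2 - |c_1|, c_2 + |c_1|]}. Supplied as a pluggable
#' strategy: the engine accepts any function with this signature.
#'
#' @param I_dend_exc Excitatory dendritic current (pA), scalar or vector.
#' @param I_dend_inh Inhibitory dendritic current magnitude (pA).
#' @param nl A \code{\link{dendriteNonlinearity}}.
#' @return Somatic current from the dendrite (pA).
#' @export
dendriteToSoma <- function(I_dend_exc, I_dend_inh, nl) {
  stopifnot(inherits(nl, "DendriteNonlinearity"))
  arg <- (I_dend_exc + nl$c3 * I_dend_inh + nl$c4) /
    (nl$c5 * exp(-I_dend_inh / nl$c6))
  nl$c1 * tanh(arg) + nl$c2
}

#' Total somatic current
#'
#' Signed sum of all current components:
#' \deqn{I_{total} = \beta_{NMDA} I_{NMDA} + I_{AMPA,ext} +
#'   \beta_{AMPA} I_{AMPA,rec} - I_{GABA} + I_{soma,dend} + I_{bg}.}
#' Components are supplied as depolarizing magnitudes; the adapter gives
#' GABA its hyperpolarizing sign. With control scaling
#' (\eqn{\beta_{NMDA} = \beta_{AMPA} = 1}) this is the plain sum.
#'
#' @param I_NMDA,I_AMPA_ext,I_AMPA_rec,I_GABA,I_soma_dend,I_bg Current
#'   components (pA), scalars or vectors of a common length.
#' @param scaling A \code{\link{stressScaling}}.
#' @return Net depolarizing current (pA).
#' @export
totalCurrent <- function(I_NMDA, I_AMPA_ext, I_AMPA_rec, I_GABA,
                         I_soma_dend = 0, I_bg = 0,
                         scaling = stressScaling()) {
  stopifnot(inherits(scaling, "StressScaling"))
  scaling$beta_NMDA * I_NMDA + I_AMPA_ext +
    scaling$beta_AMPA * I_AMPA_rec - I_GABA + I_soma_dend + I_bg
}

#' One forward-Euler membrane step
#'
#' Advances the somatic potential by
#' \eqn{\Delta V = \frac{dt}{C_m}\,(-g_L (V - V_L) + I_{total})}, where
#' \code{I_total} is the net depolarizing current from
#' \code{\link{totalCurrent}}. During the refractory period the potential is
#' held at \code{V_reset}. Crossing \code{V_th} outside the refractory
#' period fires a spike: the potential resets and the refractory clock is
#' set to \code{t + t_ref}.
#'
#' @param V Membrane potential (mV), scalar or vector.
#' @param I_total Net depolarizing current (pA), same length.
#' @param p A \code{\link{neuronParams}} (scalar use) or a list of equal
#'   length vectors \code{C_m}, \code{g_L}, \code{V_L}, \code{V_th},
#'   \code{V_reset}, \code{t_ref} (vectorized use).
#' @param dt Time step (ms), > 0 and well below \code{C_m/g_L}.
#' @param t Current time (ms), used for the refractory bookkeeping.
#' @param refractory_until Time (ms) until which each neuron is refractory.
#' @return List with \code{V}, \code{spiked} (logical) and
#'   \code{refractory_until}.
#' @export
membraneStep <- function(V, I_total, p, dt, t = 0, refractory_until = -Inf) {
  assertScalar(dt, "dt", positive = TRUE)
  Vn <- V + dt * (-p$g_L * (V - p$V_L) + I_total) / p$C_m
  if (any(!is.finite(Vn)))
    stop(sprintf("non-finite membrane potential at t = %g ms (neuron %d)",
                 t, which(!is.finite(Vn))[1]), call. = FALSE)
  vres <- rep(p$V_reset, length.out = length(Vn))
  tref <- rep(p$t_ref, length.out = length(Vn))
  refr <- t < refractory_until
  if (any(refr)) Vn[refr] <- vres[refr]
  spiked <- (Vn >= p$V_th) & !refr
  refractory_until <- rep(refractory_until, length.out = length(Vn))
  if (any(spiked)) {
    Vn[spiked] <- vres[spiked]
    refractory_until[spiked] <- t + tref[spiked]
  }
  list(V = Vn, spiked = spiked, refractory_until = refractory_until)
}
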