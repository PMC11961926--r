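#' Membrane parameters of a two-compartment integrate-and-fire neuron
#'
#' Bundles the somatic membrane constants of the leaky integrate-and-fire
#' neuron. The spike mechanism (threshold, reset, refractory period) is not
#' constrained by the membrane equation itself and is configurable; the
#' shipped defaults follow the classic cortical attractor-network choice.
#'
#' @param C_m Membrane capacitance (pF).
#' @param g_L Leak conductance (nS).
#' @param V_L Resting / reversal potential (mV); also the common driving-force
#'   reference of every synaptic current in this model.
#' @param V_th Spike threshold (mV).
#' @param V_reset Post-spike reset potential (mV).
#' @param t_ref Absolute refractory period (ms).
#' @param is_excitatory Logical flag; excitatory neurons release onto
#'   AMPA/NMDA receptors, inhibitory neurons onto GABA receptors.
#' @return A validated list of class \code{"NeuronParams"}.
#' @examples
#' p <- neuronParams()
#' p$C_m / p$g_L   # membrane time constant, ms
#' @export
neuronParams <- function(C_m = 200, g_L = 10, V_L = -70, V_th = -50,
                         V_reset = -60, t_ref = 2, is_excitatory = TRUE) {
  assertScalar(C_m, "C_m", positive = TRUE)
  assertScalar(g_L, "g_L", positive = TRUE)
  assertScalar(V_L, "V_L")
  assertScalar(V_th, "V_th")
  assertScalar(V_reset, "V_reset")
  assertScalar(t_ref, "t_ref", nonneg = TRUE)
  if (V_reset > V_th)
    stop("V_reset must be <= V_th", call. = FALSE)
  structure(list(C_m = C_m, g_L = g_L, V_L = V_L, V_th = V_th,
                 V_reset = V_reset, t_ref = t_ref,
                 is_excitatory = isTRUE(is_excitatory)),
            class = "NeuronParams")
}

#' Synaptic receptor and short-term-plasticity parameters
#'
#' Conductances, decay constants and gating-increment factors for the three
#' receptor classes, plus the facilitation/depression constants of the
#' short-term plasticity (STP) model: baseline utilization \code{U}, the
#' facilitation decay constant \code{tau_u} and the depression recovery
#' constant \code{tau_x}. \code{gamma_AMPA}, \code{gamma_NMDA} and
#' \code{gamma_I} are the per-spike gating increment factors; sweeping them
#' is how "fractional channel strength" manipulations are expressed.
#' \code{gamma_mg} and \code{beta_mg} shape the NMDA magnesium-block voltage
#' dependence \eqn{1/(1+\gamma e^{-\beta V})}.
#'
#' @param g_AMPA_ext,g_AMPA_rec,g_NMDA_rec,g_GABA Conductances (nS).
#' @param gamma_mg NMDA voltage-dependence scale (dimensionless).
#' @param beta_mg NMDA voltage-dependence slope (1/mV).
#' @param tau_AMPA,tau_NMDA,tau_GABA Gating decay constants (ms).
#' @param gamma_AMPA,gamma_NMDA,gamma_I Gating increment factors.
#' @param U Baseline utilization, in (0, 1].
#' @param tau_u Facilitation decay constant (ms).
#' @param tau_x Depression recovery constant (ms).
#' @return A validated list of class \code{"SynapseParams"}.
#' @export
synapseParams <- function(g_AMPA_ext = 5, g_AMPA_rec = 0.4, g_NMDA_rec = 1.2,
                          g_GABA = 1.0, gamma_mg = 0.2801, beta_mg = 0.062,
                          tau_AMPA = 2, tau_NMDA = 100, tau_GABA = 5,
                          gamma_AMPA = 1, gamma_NMDA = 1, gamma_I = 1,
                          U = 0.15, tau_u = 1500, tau_x = 2) {
  for (nm in c("g_AMPA_ext", "g_AMPA_rec", "g_NMDA_rec", "g_GABA"))
    assertScalar(get(nm), nm, nonneg = TRUE)
  assertScalar(gamma_mg, "gamma_mg", nonneg = TRUE)
  assertScalar(beta_mg, "beta_mg", nonneg = TRUE)
  for (nm in c("tau_AMPA", "tau_NMDA", "tau_GABA", "tau_u", "tau_x"))
    assertScalar(get(nm), nm, positive = TRUE)
  for (nm in c("gamma_AMPA", "gamma_NMDA", "gamma_I"))
    assertScalar(get(nm), nm, nonneg = TRUE)
  assertScalar(U, "U", positive = TRUE)
  if (U > 1) stop("U must be in (0, 1]", call. = FALSE)
  structure(list(g_AMPA_ext = g_AMPA_ext, g_AMPA_rec = g_AMPA_rec,
                 g_NMDA_rec = g_NMDA_rec, g_GABA = g_GABA,
                 gamma_mg = gamma_mg, beta_mg = beta_mg,
                 tau_AMPA = tau_AMPA, tau_NMDA = tau_NMDA,
                 tau_GABA = tau_GABA, gamma_AMPA = gamma_AMPA,
                 gamma_NMDA = gamma_NMDA, gamma_I = gamma_I,
                 U = U, tau_u = tau_u, tau_x = tau_x),
            class = "SynapseParams")
}

#' Per-presynaptic-neuron synaptic state
#'
#' Open-channel gating fractions for the three receptor classes and the two
#' short-term-plasticity variables: utilization \code{u} (initialized at the
#' baseline \code{U}) and available resources \code{x} (initialized at 1).
#'
#' @param s_AMPA,s_NMDA,s_GABA Gating fractions (>= 0; s_NMDA in [0, 1]).
#' @param u Utilization.
#' @param x Available resources, in [0, 1].
#' @return A list of class \code{"SynapseState"}.
#' @export
synapseState <- function(s_AMPA = 0, s_NMDA = 0, s_GABA = 0, u = 0.15, x = 1) {
  for (nm in c("s_AMPA", "s_NMDA", "s_GABA"))
    assertScalar(get(nm), nm, nonneg = TRUE)
  assertFraction(s_NMDA, "s_NMDA")
  assertFraction(u, "u")
  assertFraction(x, "x")
  structure(list(s_AMPA = s_AMPA, s_NMDA = s_NMDA, s_GABA = s_GABA,
                 u = u, x = x),
            class = "SynapseState")
}

#' Dendritic spine counts and inhibitory input fractions
#'
#' Mean dendritic spine counts for excitatory neurons (\code{EXN}) and for
#' bipolar (\code{BP}) and multipolar (\code{MP}) interneurons, together with
#' the inhibitory input fraction i/(i+e) on each type and the chronic-stress
#' spine-loss fraction \code{fac} (0.16 under chronic stress, 0 otherwise).
#' These feed the effective synapse-count multipliers via
#' \code{\link{effectiveSynapseCounts}}. The shipped numeric defaults are
#' synthetic stand-ins at realistic orders of magnitude; the published
#' electron-microscopy tables they emulate are replaceable via configuration.
#'
#' @param EXN,BP,MP Mean spine counts (>= 0).
#' @param EXN_IN,BP_IN,MP_IN Inhibitory input fractions, in [0, 1].
#' @param fac Chronic spine-loss fraction, in [0, 1].
#' @return A list of class \code{"SpineCounts"}.
#' @export
spineCounts <- function(EXN = 20, BP = 10, MP = 15, EXN_IN = 0.2,
                        BP_IN = 0.4, MP_IN = 0.35, fac = 0) {
  for (nm in c("EXN", "BP", "MP")) assertScalar(get(nm), nm, nonneg = TRUE)
  for (nm in c("EXN_IN", "BP_IN", "MP_IN", "fac"))
    assertFraction(get(nm), nm)
  structure(list(EXN = EXN, BP = BP, MP = MP, EXN_IN = EXN_IN,
                 BP_IN = BP_IN, MP_IN = MP_IN, fac = fac),
            class = "SpineCounts")
}

#' Effective synapse-count multipliers from spine counts
#'
#' Maps dendritic spine statistics to the per-neuron receptor multipliers
#' \eqn{\mu} that scale each synaptic current. Spines carry predominantly
#' excitatory synapses, shafts predominantly inhibitory ones, so the
#' excitatory-synapse share is \code{(1 - IN)} of the spine count, split
#' equally (factor 0.5) between NMDA and AMPA receptors. The excitatory-neuron
#' GABA multiplier uses the inhibitory fraction directly. For interneurons,
#' all three receptor multipliers are the BP/MP spine sum with the same
#' halved excitatory-share form (implemented exactly as specified for the
#' GABA entry as well, not symmetrized). Chronic stress shrinks only the
#' EXN-derived entries, by the factor \code{(1 - fac)}.
#'
#' @param sc A \code{\link{spineCounts}} object.
#' @return A list of class \code{"EffectiveSynapseCounts"} with fields
#'   \code{mu_e_NMDA}, \code{mu_e_AMPA}, \code{mu_e_GABA}, \code{mu_i_NMDA},
#'   \code{mu_i_AMPA}, \code{mu_i_GABA}.
#' @examples
#' effectiveSynapseCounts(spineCounts(EXN = 100, EXN_IN = 0.2))$mu_e_NMDA # 40
#' @export
effectiveSynapseCounts <- function(sc) {
  stopifnot(inherits(sc, "SpineCounts"))
  exn <- sc$EXN * (1 - sc$fac)
  mu_i_glu <- sc$BP * (1 - sc$BP_IN) * 0.5 + sc$MP * (1 - sc$MP_IN) * 0.5
  structure(list(
    mu_e_NMDA = exn * (1 - sc$EXN_IN) * 0.5,
    mu_e_AMPA = exn * (1 - sc$EXN_IN) * 0.5,
    mu_e_GABA = exn * sc$EXN_IN,
    mu_i_NMDA = mu_i_glu,
    mu_i_AMPA = mu_i_glu,
    mu_i_GABA = mu_i_glu),
    class = "EffectiveSynapseCounts")
}

#' Dendrite-to-soma transfer nonlinearity constants
#'
#' Shape constants of the saturating dendritic transfer function
#' \eqn{I_{soma} = c_1 \tanh((I_{exc} + c_3 I_{inh} + c_4) /
#' (c_5 e^{-I_{inh}/c_6})) + c_2}. \code{c1} sets the gain (pA), \code{c2}
#' the output offset (pA), \code{c3} how inhibition shifts the inversion
#' point, \code{c4} the translation (pA), and \code{c5}, \code{c6} (> 0, pA)
#' the slope scale and its inhibition dependence.
#'
#' @param c1,c2,c3,c4,c5,c6 Shape constants; \code{c5 > 0}, \code{c6 > 0}.
#' @return A list of class \code{"DendriteNonlinearity"}.
#' @export
dendriteNonlinearity <- function(c1 = 30, c2 = 14, c3 = -1, c4 = -50,
                                 c5 = 100, c6 = 200) {
  for (nm in c("c1", "c2", "c3", "c4")) assertScalar(get(nm), nm)
  assertScalar(c5, "c5", positive = TRUE)
  assertScalar(c6, "c6", positive = TRUE)
  structure(list(c1 = c1, c2 = c2, c3 = c3, c4 = c4, c5 = c5, c6 = c6),
            class = "DendriteNonlinearity")
}

#' Stress scaling factors
#'
#' Dimensionless multipliers that express a stress condition at the dynamics
#' level: \code{beta_NMDA} and \code{beta_AMPA} scale the recurrent NMDA and
#' AMPA currents (acute stress; ratios of stressed to control EPSC
#' amplitudes), \code{gamma_I_scale} rescales the GABA channel fractional
#' strength (chronic stress), and the four \code{*_scale} entries multiply
#' within-group connection blocks. The control condition is the identity:
#' every multiplier 1.
#'
#' @param beta_NMDA,beta_AMPA Acute current multipliers (>= 0).
#' @param gamma_I_scale GABA channel fractional-strength multiplier (>= 0).
#' @param ee_scale,ie_scale,ei_scale,ii_scale Within-group connection-block
#'   multipliers (>= 0).
#' @return A list of class \code{"StressScaling"}.
#' @export
stressScaling <- function(beta_NMDA = 1, beta_AMPA = 1, gamma_I_scale = 1,
                          ee_scale = 1, ie_scale = 1, ei_scale = 1,
                          ii_scale = 1) {
  for (nm in c("beta_NMDA", "beta_AMPA", "gamma_I_scale", "ee_scale",
               "ie_scale", "ei_scale", "ii_scale"))
    assertScalar(get(nm), nm, nonneg = TRUE)
  structure(list(beta_NMDA = beta_NMDA, beta_AMPA = beta_AMPA,
                 gamma_I_scale = gamma_I_scale, ee_scale = ee_scale,
                 ie_scale = ie_scale, ei_scale = ei_scale,
                 ii_scale = ii_scale),
            class = "StressScaling")
}

isControlScaling <- function(s) {
  all(vapply(s, function(v) isTRUE(all.equal(v, 1)), logical(1)))
}

#' Operational criterion for counting a group as "sustained"
#'
#' The recall paradigm defines capacity as the number of selective groups
#' whose excitatory population keeps discharging through the delay. The
#' operationalization is configurable: a group counts if at least
#' \code{fraction_active} of its excitatory neurons fire above
#' \code{rate_threshold} Hz inside a window of length \code{window} ms ending
#' at the end of the delay epoch.
#'
#' @param window Window length (ms), taken as the tail of the delay epoch.
#' @param rate_threshold Minimum firing rate (Hz) for a neuron to count as
#'   active.
#' @param fraction_active Fraction of the group's excitatory neurons that
#'   must be active.
#' @return A list of class \code{"CapacityCriterion"}.
#' @export
capacityCriterion <- function(window = 200, rate_threshold = 10,
                              fraction_active = 0.5) {
  assertScalar(window, "window", positive = TRUE)
  assertScalar(rate_threshold, "rate_threshold", nonneg = TRUE)
  assertFraction(fraction_active, "fraction_active")
  structure(list(window = window, rate_threshold = rate_threshold,
                 fraction_active = fraction_active),
            class = "CapacityCriterion")
}
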