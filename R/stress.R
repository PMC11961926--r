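#' @include AllClasses.R params.R network.R
NULL

# Acute EPSC ratios: stressed / control amplitudes from slice recordings of
# prefrontal pyramidal neurons (forced-swim stressor). The other acute
# presets are configurable stand-ins: their published amplitudes live in
# supplementary material, so the shipped numbers are placeholders of
# plausible magnitude, replaceable per condition.
.SWIM_BETA_NMDA <- 425 / 197
.SWIM_BETA_AMPA <- 98.8 / 58.6

.ACUTE_PRESETS <- list(
  acute_swim      = list(beta_NMDA = .SWIM_BETA_NMDA,
                         beta_AMPA = .SWIM_BETA_AMPA),
  acute_restraint = list(beta_NMDA = 1.8, beta_AMPA = 1.5),
  acute_platform  = list(beta_NMDA = 1.6, beta_AMPA = 1.4))

#' Acute current multiplier from EPSC amplitudes
#'
#' The acute-stress scaling factor is the ratio of the stressed EPSC
#' amplitude to the control amplitude (actual stressed current size /
#' control current size).
#'
#' @param control_pA Control EPSC amplitude (pA), > 0.
#' @param stress_pA Stressed EPSC amplitude (pA).
#' @return The dimensionless multiplier.
#' @examples
#' acuteScalingFromEpsc(197, 425)    # NMDA, forced swim
#' acuteScalingFromEpsc(58.6, 98.8)  # AMPA, forced swim
#' @export
acuteScalingFromEpsc <- function(control_pA, stress_pA) {
  assertScalar(stress_pA, "stress_pA", nonneg = TRUE)
  if (!is.numeric(control_pA) || length(control_pA) != 1L ||
      !is.finite(control_pA) || control_pA <= 0)
    stop("control_pA must be > 0", call. = FALSE)
  stress_pA / control_pA
}

#' Construct a named stress condition
#'
#' Maps a condition name to its model transform. \code{control} is the
#' identity. The acute conditions set recurrent-current multipliers
#' (\code{beta_NMDA}, \code{beta_AMPA}) without structural change; the
#' forced-swim preset uses the measured EPSC ratios 425/197 (NMDA) and
#' 98.8/58.6 (AMPA). \code{chronic} removes \code{fac} = 0.16 of excitatory
#' dendritic spines and can rescale GABA channel strength
#' (\code{gamma_I_scale}) and within-group connection blocks.
#' \code{acute_ketamine} is modeled as the chronic base plus an NMDA
#' current-strength increase.
#'
#' @param name Condition name.
#' @param fac Spine-loss fraction; defaults to 0.16 for chronic-based
#'   conditions and 0 otherwise.
#' @param scaling Optional \code{\link{stressScaling}} overriding the
#'   preset.
#' @param ... Named scalar overrides for individual scaling fields (e.g.
#'   \code{gamma_I_scale = 1.5}, \code{ee_scale = 2}).
#' @return A \code{\linkS4class{StressCondition}}.
#' @export
stressCondition <- function(name = c("control", "acute_swim",
                                     "acute_restraint", "acute_platform",
                                     "acute_ketamine", "chronic"),
                            fac = NULL, scaling = NULL, ...) {
  name <- match.arg(name)
  base <- switch(name,
    control = list(),
    acute_swim = .ACUTE_PRESETS$acute_swim,
    acute_restraint = .ACUTE_PRESETS$acute_restraint,
    acute_platform = .ACUTE_PRESETS$acute_platform,
    acute_ketamine = list(beta_NMDA = 1.5),
    chronic = list())
  dots <- list(...)
  if (is.null(scaling))
    scaling <- do.call(stressScaling, utils::modifyList(base, dots))
  stopifnot(inherits(scaling, "StressScaling"))
  if (is.null(fac))
    fac <- if (name %in% c("chronic", "acute_ketamine")) 0.16 else 0
  methods::new("StressCondition", name = name,
               scaling = unclass(scaling), fac = fac)
}

#' Apply a stress condition to a network
#'
#' Control returns the network unchanged (bit-identical). Acute conditions
#' attach the current multipliers at the dynamics level; the weight matrix
#' and synapse counts are untouched. Chronic-based conditions recompute the
#' effective synapse counts with the spine-loss fraction \code{fac}
#' (shrinking every EXN-derived multiplier by \code{1 - fac}), multiply the
#' per-neuron GABA gating increment by \code{gamma_I_scale}, and apply any
#' within-group connection-block scaling.
#'
#' @param net A \code{\linkS4class{Network}}.
#' @param cond A \code{\linkS4class{StressCondition}}.
#' @return The transformed \code{Network}.
#' @export
applyCondition <- function(net, cond) {
  stopifnot(is(net, "Network"), is(cond, "StressCondition"))
  if (cond@name == "control") return(net)
  sc <- cond@scaling
  net@scaling <- sc
  net@condition <- cond@name
  if (cond@fac > 0) {
    sp <- do.call(spineCounts, utils::modifyList(as.list(net@spines),
                                                 list(fac = cond@fac)))
    net@spines <- unclass(sp)
    mus <- effectiveSynapseCounts(sp)
    net@mu <- data.frame(
      mu_NMDA = ifelse(net@isExc, mus$mu_e_NMDA, mus$mu_i_NMDA),
      mu_AMPA = ifelse(net@isExc, mus$mu_e_AMPA, mus$mu_i_AMPA),
      mu_GABA = ifelse(net@isExc, mus$mu_e_GABA, mus$mu_i_GABA))
  }
  if (sc$gamma_I_scale != 1)
    net@synapses$gamma_I <- net@synapses$gamma_I * sc$gamma_I_scale
  for (blk in c("ee", "ie", "ei", "ii")) {
    f <- sc[[paste0(blk, "_scale")]]
    if (f != 1) net <- scaleConnections(net, toupper(blk), f)
  }
  methods::validObject(net)
  net
}

#' Define a sweep grid
#'
#' A full factorial grid over named axes, each axis a numeric value vector,
#' run for \code{replicates} seeded repeats per point. Recognized axes:
#' \code{gamma_AMPA}, \code{gamma_NMDA}, \code{gamma_I} (multipliers on the
#' corresponding gating increment factors), \code{beta_NMDA},
#' \code{beta_AMPA} (acute current multipliers), \code{ee_scale},
#' \code{ie_scale}, \code{ei_scale}, \code{ii_scale} (within-group block
#' multipliers) and \code{fac} (spine-loss fraction).
#'
#' @param ... Named numeric axis vectors.
#' @param replicates Seeded repeats per grid point.
#' @return A list of class \code{"SweepGrid"} with a \code{points}
#'   data.frame (one row per grid point).
#' @export
sweepGrid <- function(..., replicates = 3) {
  axes <- list(...)
  if (length(axes) == 0 || is.null(names(axes)) || any(names(axes) == ""))
    stop("sweepGrid needs at least one named axis", call. = FALSE)
  known <- c("gamma_AMPA", "gamma_NMDA", "gamma_I", "beta_NMDA",
             "beta_AMPA", "ee_scale", "ie_scale", "ei_scale", "ii_scale",
             "fac")
  bad <- setdiff(names(axes), known)
  if (length(bad))
    stop("unknown sweep axes: ", paste(bad, collapse = ", "), call. = FALSE)
  for (nm in names(axes))
    if (!is.numeric(axes[[nm]]) || length(axes[[nm]]) == 0)
      stop(sprintf("axis '%s' must be a non-empty numeric vector", nm),
           call. = FALSE)
  assertScalar(replicates, "replicates", positive = TRUE)
  structure(list(axes = axes, replicates = as.integer(replicates),
                 points = expand.grid(axes, KEEP.OUT.ATTRS = FALSE)),
            class = "SweepGrid")
}

# Apply one sweep axis value on top of a (condition-transformed) network.
applySweepAxis <- function(net, axis, value) {
  switch(axis,
    gamma_AMPA = { net@synapses$gamma_AMPA <- net@synapses$gamma_AMPA * value; net },
    gamma_NMDA = { net@synapses$gamma_NMDA <- net@synapses$gamma_NMDA * value; net },
    gamma_I    = { net@synapses$gamma_I <- net@synapses$gamma_I * value; net },
    beta_NMDA  = { net@scaling$beta_NMDA <- net@scaling$beta_NMDA * value; net },
    beta_AMPA  = { net@scaling$beta_AMPA <- net@scaling$beta_AMPA * value; net },
    ee_scale   = scaleConnections(net, "EE", value),
    ie_scale   = scaleConnections(net, "IE", value),
    ei_scale   = scaleConnections(net, "EI", value),
    ii_scale   = scaleConnections(net, "II", value),
    fac        = {
      sp <- do.call(spineCounts, utils::modifyList(as.list(net@spines),
                                                   list(fac = value)))
      mus <- effectiveSynapseCounts(sp)
      net@spines <- unclass(sp)
      net@mu <- data.frame(
        mu_NMDA = ifelse(net@isExc, mus$mu_e_NMDA, mus$mu_i_NMDA),
        mu_AMPA = ifelse(net@isExc, mus$mu_e_AMPA, mus$mu_i_AMPA),
        mu_GABA = ifelse(net@isExc, mus$mu_e_GABA, mus$mu_i_GABA))
      net
    },
    stop("unknown sweep axis: ", axis, call. = FALSE))
}
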