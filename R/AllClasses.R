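#' @include utils.R params.R
NULL

setClassUnion("listOrNULL", c("list", "NULL"))

#' Network of selective excitatory/inhibitory neuron groups
#'
#' S4 container for a structured spiking network: group labels, neuron types,
#' the weight matrix (rows = postsynaptic, columns = presynaptic, zero = no
#' synapse), per-neuron membrane and synapse parameter tables, per-neuron
#' effective synapse-count multipliers, the active stress scaling, and the
#' build configuration. Construct with \code{\link{buildNetwork}}.
#'
#' @slot groupOf Integer group label per neuron.
#' @slot isExc Logical; TRUE for excitatory neurons.
#' @slot W Numeric weight matrix, post x pre; respects Dale's principle.
#' @slot neurons data.frame of per-neuron membrane parameters
#'   (C_m, g_L, V_L, V_th, V_reset, t_ref).
#' @slot synapses data.frame of per-neuron synapse/STP parameters (the
#'   presynaptic neuron owns the release parameters; the postsynaptic neuron
#'   owns conductances and Mg-block constants).
#' @slot mu data.frame of per-neuron receptor multipliers
#'   (mu_NMDA, mu_AMPA, mu_GABA).
#' @slot spines \code{\link{spineCounts}} the multipliers derive from.
#' @slot nonlinearity \code{\link{dendriteNonlinearity}} constants.
#' @slot scaling \code{\link{stressScaling}} currently applied.
#' @slot condition Name of the applied stress condition.
#' @slot I_bg Background somatic current (pA).
#' @slot config The \code{networkConfig} list used to build the network.
#' @slot seed Integer build seed.
#' @export
setClass("Network", representation(
  groupOf = "integer", isExc = "logical", W = "matrix",
  neurons = "data.frame", synapses = "data.frame", mu = "data.frame",
  spines = "list", nonlinearity = "list", scaling = "list",
  condition = "character", I_bg = "numeric", config = "list",
  seed = "integer"))

setValidity("Network", function(object) {
  n <- length(object@groupOf)
  msg <- character(0)
  if (length(object@isExc) != n) msg <- c(msg, "groupOf/isExc length mismatch")
  if (!all(dim(object@W) == c(n, n))) msg <- c(msg, "W must be n x n")
  if (nrow(object@neurons) != n || nrow(object@synapses) != n ||
      nrow(object@mu) != n)
    msg <- c(msg, "parameter tables must have one row per neuron")
  if (n > 0 && any(diag(object@W) != 0)) msg <- c(msg, "self-connections present")
  if (n > 0) {
    excCols <- object@W[, object@isExc, drop = FALSE]
    inhCols <- object@W[, !object@isExc, drop = FALSE]
    if (any(excCols < 0) || any(inhCols < 0))
      msg <- c(msg, "weights must be non-negative magnitudes")
  }
  if (length(msg)) msg else TRUE
})

#' Short-term recall stimulus protocol
#'
#' Epochs run contiguously: fixation, memory (long input stimulus), delay,
#' cue (brief probe), then an optional post-cue observation period. External
#' Poisson drive targets all excitatory neurons at the epoch's rate.
#'
#' @slot t_fixation,t_memory,t_delay,t_cue,t_post Epoch durations (ms).
#' @slot rate_memory,rate_cue,rate_background Poisson rates (Hz) of the
#'   aggregate external AMPA drive per excitatory neuron.
#' @export
setClass("StimulusProtocol", representation(
  t_fixation = "numeric", t_memory = "numeric", t_delay = "numeric",
  t_cue = "numeric", t_post = "numeric", rate_memory = "numeric",
  rate_cue = "numeric", rate_background = "numeric"))

setValidity("StimulusProtocol", function(object) {
  d <- c(object@t_fixation, object@t_memory, object@t_delay, object@t_cue,
         object@t_post)
  r <- c(object@rate_memory, object@rate_cue, object@rate_background)
  if (any(!is.finite(d)) || any(d < 0)) return("durations must be >= 0")
  if (any(!is.finite(r)) || any(r < 0)) return("rates must be >= 0")
  TRUE
})

#' A named stress condition
#'
#' Couples a condition name with its model transform: acute conditions carry
#' EPSC-ratio current multipliers (no structural change); the chronic
#' condition removes a fraction \code{fac} of excitatory dendritic spines and
#' may rescale GABA channel strength or within-group connection blocks.
#'
#' @slot name One of control, acute_swim, acute_restraint, acute_platform,
#'   acute_ketamine, chronic.
#' @slot scaling A \code{\link{stressScaling}} list.
#' @slot fac Spine-loss fraction in [0, 1].
#' @export
setClass("StressCondition", representation(
  name = "character", scaling = "list", fac = "numeric"))

setValidity("StressCondition", function(object) {
  if (length(object@name) != 1L) return("name must be length 1")
  if (!is.finite(object@fac) || object@fac < 0 || object@fac > 1)
    return("fac must lie in [0, 1]")
  if (object@name == "control" &&
      (!isControlScaling(object@scaling) || object@fac != 0))
    return("control condition requires identity scaling and fac = 0")
  TRUE
})

#' Result of one simulation run
#'
#' Spike raster, per-population mean synaptic-current traces (and optionally
#' per-neuron current arrays), plus everything needed to reproduce and
#' analyze the run: protocol, condition name, seed, time step and a
#' configuration hash.
#'
#' @slot raster data.frame with columns \code{time_ms}, \code{neuron}.
#' @slot currents data.frame with columns \code{time_ms}, \code{population}
#'   ("E"/"I"), \code{receptor} ("AMPA_ext"/"AMPA_rec"/"NMDA"/"GABA"),
#'   \code{value} (pA, population mean magnitude at the recording stride).
#' @slot neuronCurrents Optional list of receptor-named matrices
#'   (time x neuron), populated when per-neuron recording was requested.
#' @slot protocol The \code{StimulusProtocol} used.
#' @slot condition Condition name.
#' @slot groupOf,isExc Copied from the simulated network so the analysis
#'   layer can work from the result alone.
#' @slot dt Integration step (ms).
#' @slot span Simulated span (ms).
#' @slot seed Input-stream seed.
#' @slot configHash md5 of the effective run configuration.
#' @export
setClass("SimulationResult", representation(
  raster = "data.frame", currents = "data.frame",
  neuronCurrents = "listOrNULL", protocol = "StimulusProtocol",
  condition = "character", groupOf = "integer", isExc = "logical",
  dt = "numeric", span = "numeric", seed = "integer",
  configHash = "character"))

setValidity("SimulationResult", function(object) {
  r <- object@raster
  if (!all(c("time_ms", "neuron") %in% names(r)))
    return("raster needs columns time_ms, neuron")
  if (nrow(r) && (min(r$time_ms) < 0 || max(r$time_ms) > object@span))
    return("spike times outside simulated span")
  cu <- object@currents
  if (nrow(cu) && !all(c("time_ms", "population", "receptor", "value")
                       %in% names(cu)))
    return("currents needs columns time_ms, population, receptor, value")
  TRUE
})

# ---- accessors -------------------------------------------------------------

#' @describeIn SimulationResult-class Spike raster as a data.frame.
#' @param object A \code{SimulationResult} or \code{Network}.
#' @export
setGeneric("spikeRaster", function(object) standardGeneric("spikeRaster"))
#' @export
setMethod("spikeRaster", "SimulationResult", function(object) object@raster)

#' @describeIn SimulationResult-class Population mean current traces.
#' @export
setGeneric("currentTraces", function(object) standardGeneric("currentTraces"))
#' @export
setMethod("currentTraces", "SimulationResult", function(object) object@currents)

#' Per-neuron table (id, group, type) of a network or result
#'
#' @param object A \code{Network} or \code{SimulationResult}.
#' @return data.frame with columns \code{neuron}, \code{group},
#'   \code{is_exc}.
#' @export
setGeneric("neuronTable", function(object) standardGeneric("neuronTable"))
#' @export
setMethod("neuronTable", "Network", function(object)
  data.frame(neuron = seq_along(object@groupOf), group = object@groupOf,
             is_exc = object@isExc))
#' @export
setMethod("neuronTable", "SimulationResult", function(object)
  data.frame(neuron = seq_along(object@groupOf), group = object@groupOf,
             is_exc = object@isExc))

#' Number of selective groups
#' @param object A \code{Network} or \code{SimulationResult}.
#' @export
setGeneric("nGroups", function(object) standardGeneric("nGroups"))
#' @export
setMethod("nGroups", "Network", function(object)
  length(unique(object@groupOf)))
#' @export
setMethod("nGroups", "SimulationResult", function(object)
  length(unique(object@groupOf)))

#' Weight matrix accessor
#' @param object A \code{Network}.
#' @export
setGeneric("weightMatrix", function(object) standardGeneric("weightMatrix"))
#' @export
setMethod("weightMatrix", "Network", function(object) object@W)

#' Condition name accessor
#' @param object A \code{Network}, \code{StressCondition} or
#'   \code{SimulationResult}.
#' @export
setGeneric("conditionName", function(object) standardGeneric("conditionName"))
#' @export
setMethod("conditionName", "Network", function(object) object@condition)
#' @export
setMethod("conditionName", "StressCondition", function(object) object@name)
#' @export
setMethod("conditionName", "SimulationResult", function(object)
  object@condition)

#' Total protocol span in ms
#' @param object A \code{StimulusProtocol}.
#' @export
setGeneric("protocolSpan", function(object) standardGeneric("protocolSpan"))
#' @export
setMethod("protocolSpan", "StimulusProtocol", function(object)
  object@t_fixation + object@t_memory + object@t_delay + object@t_cue +
    object@t_post)

# ---- show ------------------------------------------------------------------

setMethod("show", "Network", function(object) {
  n <- length(object@groupOf)
  cat(sprintf("Network: %d neurons (%d E, %d I) in %d groups\n",
              n, sum(object@isExc), sum(!object@isExc),
              length(unique(object@groupOf))))
  cat(sprintf("  mode: %s | condition: %s | edges: %d\n",
              object@config$mode %||% "?", object@condition,
              sum(object@W != 0)))
})

setMethod("show", "StimulusProtocol", function(object) {
  cat(sprintf(paste0("StimulusProtocol: fixation %g | memory %g | delay %g",
                     " | cue %g | post %g ms\n"),
              object@t_fixation, object@t_memory, object@t_delay,
              object@t_cue, object@t_post))
  cat(sprintf("  rates (Hz): memory %g, cue %g, background %g\n",
              object@rate_memory, object@rate_cue, object@rate_background))
})

setMethod("show", "StressCondition", function(object) {
  cat(sprintf("StressCondition '%s': fac = %g\n", object@name, object@fac))
  s <- object@scaling
  cat(sprintf("  beta_NMDA %g | beta_AMPA %g | gamma_I_scale %g | EE %g\n",
              s$beta_NMDA, s$beta_AMPA, s$gamma_I_scale, s$ee_scale))
})

setMethod("show", "SimulationResult", function(object) {
  cat(sprintf("SimulationResult: %d spikes over %g ms\n",
              nrow(object@raster), object@span))
  cat(sprintf("  condition: %s | seed: %d | hash: %s\n",
              object@condition, object@seed,
              substr(object@configHash, 1, 8)))
})

`%||%` <- function(a, b) if (is.null(a)) b else a
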