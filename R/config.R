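#' @include network.R protocol.R stress.R analysis.R
NULL

#' Default run configuration
#'
#' The full schema of a run configuration as a named list; YAML files read
#' by \code{\link{readRunConfig}} are validated against this structure
#' (unknown keys are rejected) and merged over it.
#'
#' @return Named list with entries \code{seed}, \code{network},
#'   \code{protocol}, \code{condition}, \code{engine}, \code{analysis},
#'   \code{sweep}.
#' @export
defaultRunConfig <- function() {
  cfg <- unclass(networkConfig())
  cfg$neuron_exc$is_excitatory <- NULL
  cfg$neuron_inh$is_excitatory <- NULL
  list(
    seed = 1L,
    network = cfg,
    protocol = list(t_fixation = 1000, t_memory = 400, t_delay = 1000,
                    t_cue = 5, t_post = 500, rate_memory = 900,
                    rate_cue = 900, rate_background = 0, ramp_start = 1),
    condition = list(name = "control", fac = NULL, overrides = list()),
    engine = list(dt = 0.05, record_stride = 1,
                  record_neuron_currents = FALSE),
    analysis = list(criterion = list(window = 200, rate_threshold = 10,
                                     fraction_active = 0.5),
                    timescale = list(bin = 50, max_lag_windows = 20,
                                     pool = "units")),
    sweep = list(replicates = 3, axes = list()))
}

checkKeys <- function(user, template, path = "") {
  if (!is.list(user)) return(invisible())
  # open-ended maps: sweep axes and condition overrides carry their own
  # controlled vocabularies, checked downstream
  open <- c("sweep.axes", "condition.overrides")
  if (sub("^\\.", "", path) %in% open) return(invisible())
  unknown <- setdiff(names(user), names(template))
  if (length(unknown))
    stop(sprintf("unknown config key%s: %s",
                 if (length(unknown) > 1) "s" else "",
                 paste0(sub("^\\.", "", path), ".", unknown,
                        collapse = ", ")), call. = FALSE)
  for (nm in names(user))
    if (is.list(template[[nm]]))
      checkKeys(user[[nm]], template[[nm]], paste0(path, ".", nm))
  invisible()
}

mergeConfig <- function(base, user) {
  for (nm in names(user)) {
    if (is.list(user[[nm]]) && is.list(base[[nm]]) &&
        !nm %in% c("axes", "overrides")) {
      base[[nm]] <- mergeConfig(base[[nm]], user[[nm]])
    } else {
      base[[nm]] <- user[[nm]]
    }
  }
  base
}

#' Read and validate a run configuration
#'
#' Loads a YAML run configuration, rejects unknown keys, and merges the
#' file over \code{\link{defaultRunConfig}}.
#'
#' @param path YAML file path.
#' @return The merged configuration list, of class \code{"RunConfig"}.
#' @export
readRunConfig <- function(path) {
  if (!file.exists(path)) stop("config not found: ", path, call. = FALSE)
  user <- yaml::read_yaml(path)
  if (is.null(user)) user <- list()
  tmpl <- defaultRunConfig()
  checkKeys(user, tmpl)
  cfg <- mergeConfig(tmpl, user)
  structure(cfg, class = "RunConfig")
}

#' Instantiate model objects from a run configuration
#'
#' Builds the network (from the config's network section and seed), the
#' stimulus protocol and the stress condition a configuration describes.
#'
#' @param cfg A \code{"RunConfig"} list (see \code{\link{readRunConfig}}).
#' @return List with \code{net}, \code{proto}, \code{cond},
#'   \code{criterion}, \code{grid} (NULL when no axes), \code{engine},
#'   \code{seed}.
#' @export
buildFromConfig <- function(cfg) {
  nc <- cfg$network
  netCfg <- networkConfig(
    n_groups = nc$n_groups, n_exc_per_group = nc$n_exc_per_group,
    n_inh_per_group = nc$n_inh_per_group, mode = nc$mode,
    p_connect = nc$p_connect, weights = nc$weights,
    neuron_exc = nc$neuron_exc[.NEURON_FIELDS],
    neuron_inh = nc$neuron_inh[.NEURON_FIELDS],
    synapse = nc$synapse[intersect(names(nc$synapse), .SYN_FIELDS)],
    spines = nc$spines, nonlinearity = nc$nonlinearity, I_bg = nc$I_bg,
    heterogeneity_cv = nc$heterogeneity_cv, hom_band = nc$hom_band)
  net <- buildNetwork(netCfg, cfg$seed)
  pr <- cfg$protocol
  proto <- stimulusProtocol(t_fixation = pr$t_fixation,
                            t_memory = pr$t_memory, t_delay = pr$t_delay,
                            t_cue = pr$t_cue, t_post = pr$t_post,
                            rate_memory = pr$rate_memory,
                            rate_cue = pr$rate_cue,
                            rate_background = pr$rate_background,
                            ramp_start = pr$ramp_start)
  cond <- do.call(stressCondition,
                  c(list(name = cfg$condition$name,
                         fac = cfg$condition$fac),
                    cfg$condition$overrides))
  cr <- cfg$analysis$criterion
  criterion <- capacityCriterion(window = cr$window,
                                 rate_threshold = cr$rate_threshold,
                                 fraction_active = cr$fraction_active)
  grid <- NULL
  if (length(cfg$sweep$axes))
    grid <- do.call(sweepGrid, c(cfg$sweep$axes,
                                 list(replicates = cfg$sweep$replicates)))
  list(net = net, proto = proto, cond = cond, criterion = criterion,
       grid = grid, engine = cfg$engine, seed = cfg$seed)
}

#' Path to a shipped example configuration
#'
#' Shipped examples: \code{control}, \code{acute_swim} (forced-swim EPSC
#' ratios), \code{chronic} (16\% spine loss) and \code{chronic_enhanced_EE}
#' (chronic plus strengthened within-group excitatory coupling, the
#' inhibition-mediated-competition demonstration).
#'
#' @param name Example name.
#' @return File path inside the installed package.
#' @export
exampleConfig <- function(name = c("control", "acute_swim", "chronic",
                                   "chronic_enhanced_EE")) {
  name <- match.arg(name)
  p <- system.file("extdata", "configs", paste0(name, ".yaml"),
                   package = "stresswm", mustWork = TRUE)
  p
}
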