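#' @include AllClasses.R params.R
NULL

#' Configuration of the selective-group network
#'
#' Describes a network of \code{n_groups} selective groups, each holding
#' \code{n_exc_per_group} excitatory and \code{n_inh_per_group} inhibitory
#' neurons. Connectivity is Bernoulli per block; block probabilities and
#' weight means distinguish within-group from between-group connections.
#' Within-group excitatory coupling is stronger than between-group coupling
#' (the selectivity structure), while inhibition projects more densely
#' between groups than within (the competition mechanism that makes capacity
#' smaller than the number of structural groups). In heterogeneous mode,
#' neuron/synapse parameters and weights are drawn from truncated Gaussians
#' around their means with coefficient of variation \code{heterogeneity_cv};
#' in homogeneous mode everything is drawn uniformly within
#' \code{hom_band} of the mean with no type-specific electrophysiology.
#' Numeric defaults are documented stand-ins at biological orders of
#' magnitude, not values from the (unavailable) published tables they
#' emulate; all are replaceable through this configuration.
#'
#' @param n_groups Number of selective groups.
#' @param n_exc_per_group,n_inh_per_group Neurons per group by type.
#' @param mode "heterogeneous" or "homogeneous".
#' @param p_connect Named list of Bernoulli block probabilities:
#'   \code{ee_within, ee_between, ei_within, ei_between, ie_within,
#'   ie_between, ii_within, ii_between} (pre-post order: \code{ie} is
#'   inhibitory onto excitatory).
#' @param weights Named list of block weight means: \code{ee_within,
#'   ee_between, ie, ei, ii}; \code{ee_within} must exceed
#'   \code{ee_between}.
#' @param neuron_exc,neuron_inh Mean membrane parameters by type (named
#'   lists understood by \code{\link{neuronParams}}).
#' @param synapse Mean synapse parameters (named list understood by
#'   \code{\link{synapseParams}}).
#' @param spines A named list understood by \code{\link{spineCounts}}.
#' @param nonlinearity A named list understood by
#'   \code{\link{dendriteNonlinearity}}.
#' @param I_bg Background somatic current (pA); sets the subthreshold
#'   operating point above the resting potential.
#' @param heterogeneity_cv Coefficient of variation of heterogeneous draws.
#' @param hom_band Half-width (relative) of homogeneous uniform draws.
#' @return A validated list of class \code{"NetworkConfig"}.
#' @export
networkConfig <- function(n_groups = 4, n_exc_per_group = 40,
                          n_inh_per_group = 10,
                          mode = c("heterogeneous", "homogeneous"),
                          p_connect = list(ee_within = 0.35, ee_between = 0.1,
                                           ei_within = 0.35, ei_between = 0.1,
                                           ie_within = 0.15, ie_between = 0.15,
                                           ii_within = 0.1, ii_between = 0.1),
                          weights = list(ee_within = 1, ee_between = 0.25,
                                         ie = 0.5, ei = 1, ii = 0.5),
                          neuron_exc = list(C_m = 200, g_L = 10, V_L = -70,
                                            V_th = -50, V_reset = -60,
                                            t_ref = 2),
                          neuron_inh = list(C_m = 100, g_L = 10, V_L = -70,
                                            V_th = -50, V_reset = -60,
                                            t_ref = 1),
                          synapse = list(g_NMDA_rec = 0.9),
                          spines = list(),
                          nonlinearity = list(), I_bg = 120,
                          heterogeneity_cv = 0.1, hom_band = 0.1) {
  mode <- match.arg(mode)
  assertScalar(n_groups, "n_groups", positive = TRUE)
  assertScalar(n_exc_per_group, "n_exc_per_group", positive = TRUE)
  assertScalar(n_inh_per_group, "n_inh_per_group", positive = TRUE)
  pc <- utils::modifyList(formals(networkConfig)$p_connect |> eval(),
                          p_connect)
  for (nm in names(pc)) assertFraction(pc[[nm]], paste0("p_connect$", nm))
  wt <- utils::modifyList(formals(networkConfig)$weights |> eval(), weights)
  for (nm in names(wt)) assertScalar(wt[[nm]], paste0("weights$", nm),
                                     nonneg = TRUE)
  if (wt$ee_within <= wt$ee_between)
    stop("weights$ee_within must exceed weights$ee_between", call. = FALSE)
  assertScalar(I_bg, "I_bg")
  assertFraction(heterogeneity_cv, "heterogeneity_cv")
  assertFraction(hom_band, "hom_band")
  syn <- do.call(synapseParams, synapse)
  sp <- do.call(spineCounts, spines)
  nl <- do.call(dendriteNonlinearity, nonlinearity)
  ne <- do.call(neuronParams, c(neuron_exc, list(is_excitatory = TRUE)))
  ni <- do.call(neuronParams, c(neuron_inh, list(is_excitatory = FALSE)))
  structure(list(n_groups = as.integer(n_groups),
                 n_exc_per_group = as.integer(n_exc_per_group),
                 n_inh_per_group = as.integer(n_inh_per_group),
                 mode = mode, p_connect = pc, weights = wt,
                 neuron_exc = unclass(ne), neuron_inh = unclass(ni),
                 synapse = unclass(syn), spines = unclass(sp),
                 nonlinearity = unclass(nl), I_bg = I_bg,
                 heterogeneity_cv = heterogeneity_cv, hom_band = hom_band),
            class = "NetworkConfig")
}

.NEURON_FIELDS <- c("C_m", "g_L", "V_L", "V_th", "V_reset", "t_ref")
.SYN_FIELDS <- c("g_AMPA_ext", "g_AMPA_rec", "g_NMDA_rec", "g_GABA",
                 "gamma_mg", "beta_mg", "tau_AMPA", "tau_NMDA", "tau_GABA",
                 "gamma_AMPA", "gamma_NMDA", "gamma_I", "U", "tau_u", "tau_x")
# parameters that are physically positive and get a truncation floor
.POSITIVE_FIELDS <- c("C_m", "g_L", "t_ref", .SYN_FIELDS)
# membrane potentials get absolute jitter (mV), not relative: a coefficient
# of variation on a quantity whose zero is arbitrary would be meaningless
.MV_FIELDS <- c("V_L", "V_th", "V_reset")
.MV_SD <- 2

drawParam <- function(n, mean, cv, mode, band, mv = FALSE) {
  if (mv) {
    if (mode == "heterogeneous") return(rnorm(n, mean, .MV_SD))
    return(runif(n, mean - .MV_SD, mean + .MV_SD))
  }
  if (mean == 0) return(rep(0, n))
  if (mode == "heterogeneous") {
    sd <- abs(mean) * cv
    if (sd == 0) return(rep(mean, n))
    rnorm(n, mean, sd)
  } else {
    runif(n, mean * (1 - band), mean * (1 + band))
  }
}

#' Build a network realization
#'
#' Draws Bernoulli connectivity per probability block, block weights and
#' per-neuron parameters, deterministically for a given seed. Connectivity
#' and heterogeneity use separate derived seed streams, so parameter sweeps
#' can share a network realization while varying only input noise.
#'
#' @param cfg A \code{\link{networkConfig}}.
#' @param seed Integer master seed.
#' @return A \code{\linkS4class{Network}} in the control condition.
#' @examples
#' net <- buildNetwork(networkConfig(n_exc_per_group = 4,
#'                                   n_inh_per_group = 1), seed = 1)
#' nGroups(net)
#' @export
buildNetwork <- function(cfg, seed) {
  stopifnot(inherits(cfg, "NetworkConfig"))
  gsz <- cfg$n_exc_per_group + cfg$n_inh_per_group
  n <- cfg$n_groups * gsz
  groupOf <- rep(seq_len(cfg$n_groups), each = gsz)
  isExc <- rep(c(rep(TRUE, cfg$n_exc_per_group),
                 rep(FALSE, cfg$n_inh_per_group)), cfg$n_groups)

  # block lookups: p[pre_type, post_type, same_group]
  same <- outer(groupOf, groupOf, "==")          # post x pre
  preE <- matrix(isExc, n, n, byrow = TRUE)      # pre type per column
  postE <- matrix(isExc, n, n)
  pc <- cfg$p_connect
  P <- matrix(0, n, n)
  P[preE & postE & same] <- pc$ee_within
  P[preE & postE & !same] <- pc$ee_between
  P[preE & !postE & same] <- pc$ei_within
  P[preE & !postE & !same] <- pc$ei_between
  P[!preE & postE & same] <- pc$ie_within
  P[!preE & postE & !same] <- pc$ie_between
  P[!preE & !postE & same] <- pc$ii_within
  P[!preE & !postE & !same] <- pc$ii_between

  wt <- cfg$weights
  Wmean <- matrix(0, n, n)
  Wmean[preE & postE & same] <- wt$ee_within
  Wmean[preE & postE & !same] <- wt$ee_between
  Wmean[preE & !postE] <- wt$ei
  Wmean[!preE & postE] <- wt$ie
  Wmean[!preE & !postE] <- wt$ii

  W <- withStream(seed, "connectivity", {
    adj <- matrix(runif(n * n), n, n) < P
    diag(adj) <- FALSE
    wdraw <- if (cfg$mode == "heterogeneous") {
      matrix(rtruncnorm(n * n, 1, cfg$heterogeneity_cv), n, n)
    } else {
      matrix(runif(n * n, 1 - cfg$hom_band, 1 + cfg$hom_band), n, n)
    }
    ifelse(adj, Wmean * wdraw, 0)
  })

  mus <- effectiveSynapseCounts(do.call(spineCounts, cfg$spines))
  tabs <- withStream(seed, "heterogeneity", {
    neurons <- as.data.frame(lapply(stats::setNames(nm = .NEURON_FIELDS),
      function(f) {
        meanE <- cfg$neuron_exc[[f]]
        meanI <- cfg$neuron_inh[[f]]
        # homogeneous mode makes no type distinction
        if (cfg$mode == "homogeneous") meanI <- meanE
        mv <- f %in% .MV_FIELDS
        x <- numeric(length(isExc))
        x[isExc] <- drawParam(sum(isExc), meanE, cfg$heterogeneity_cv,
                              cfg$mode, cfg$hom_band, mv = mv)
        x[!isExc] <- drawParam(sum(!isExc), meanI, cfg$heterogeneity_cv,
                               cfg$mode, cfg$hom_band, mv = mv)
        if (f %in% .POSITIVE_FIELDS) x <- pmax(x, 1e-6)
        x
      }))
    synapses <- as.data.frame(lapply(stats::setNames(nm = .SYN_FIELDS),
      function(f) {
        x <- drawParam(length(isExc), cfg$synapse[[f]],
                       cfg$heterogeneity_cv, cfg$mode, cfg$hom_band)
        pmax(x, 1e-9)
      }))
    list(neurons = neurons, synapses = synapses)
  })
  neurons <- tabs$neurons
  synapses <- tabs$synapses
  # keep the spike mechanism ordered after jitter
  neurons$V_reset <- pmin(neurons$V_reset, neurons$V_th)
  # U is a fraction
  synapses$U <- pmin(synapses$U, 1)

  mu <- data.frame(
    mu_NMDA = ifelse(isExc, mus$mu_e_NMDA, mus$mu_i_NMDA),
    mu_AMPA = ifelse(isExc, mus$mu_e_AMPA, mus$mu_i_AMPA),
    mu_GABA = ifelse(isExc, mus$mu_e_GABA, mus$mu_i_GABA))

  methods::new("Network", groupOf = as.integer(groupOf), isExc = isExc,
               W = W, neurons = neurons, synapses = synapses, mu = mu,
               spines = cfg$spines, nonlinearity = cfg$nonlinearity,
               scaling = unclass(stressScaling()), condition = "control",
               I_bg = cfg$I_bg, config = unclass(cfg),
               seed = as.integer(seed))
}

#' Scale a within-group connection block
#'
#' Multiplies the weights of the named within-group block (EE, IE, EI or II;
#' pre-post order, so IE is inhibitory onto excitatory) by \code{factor},
#' leaving between-group connections and every other block untouched.
#' Composable: scaling by a then b equals scaling by a*b.
#'
#' @param net A \code{\linkS4class{Network}}.
#' @param which One of "EE", "IE", "EI", "II".
#' @param factor Non-negative multiplier.
#' @return The modified \code{Network}.
#' @export
scaleConnections <- function(net, which = c("EE", "IE", "EI", "II"), factor) {
  stopifnot(is(net, "Network"))
  which <- match.arg(which)
  assertScalar(factor, "factor", nonneg = TRUE)
  n <- length(net@groupOf)
  same <- outer(net@groupOf, net@groupOf, "==")
  preE <- matrix(net@isExc, n, n, byrow = TRUE)
  postE <- matrix(net@isExc, n, n)
  mask <- switch(which,
                 EE = preE & postE,
                 IE = !preE & postE,
                 EI = preE & !postE,
                 II = !preE & !postE) & same
  net@W[mask] <- net@W[mask] * factor
  methods::validObject(net)
  net
}

# ---- serialization ---------------------------------------------------------

#' Write / read a network as plain text
#'
#' \code{writeNetwork} writes three files under \code{prefix}: a columnar
#' edge list (\code{<prefix>_edges.tsv}: pre, post, weight, pre type), a
#' neuron table (\code{<prefix>_neurons.tsv}: group, type, all per-neuron
#' parameters and receptor multipliers) and a JSON metadata sidecar
#' (\code{<prefix>_meta.json}: condition, scaling, background current,
#' nonlinearity, spine counts, build config, seed). Numbers are written at
#' full precision, so \code{readNetwork} round-trips exactly.
#'
#' @param net A \code{\linkS4class{Network}}.
#' @param prefix File path prefix.
#' @return \code{writeNetwork}: the prefix, invisibly. \code{readNetwork}:
#'   the reconstructed \code{Network}.
#' @export
writeNetwork <- function(net, prefix) {
  stopifnot(is(net, "Network"))
  idx <- which(net@W != 0, arr.ind = TRUE)
  edges <- data.frame(pre = idx[, 2], post = idx[, 1],
                      weight = fmtNum(net@W[idx]),
                      pre_type = ifelse(net@isExc[idx[, 2]], "E", "I"))
  edges <- edges[order(edges$pre, edges$post), ]
  write.table(edges, paste0(prefix, "_edges.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  ntab <- cbind(data.frame(neuron = seq_along(net@groupOf),
                           group = net@groupOf,
                           is_exc = net@isExc),
                as.data.frame(lapply(net@neurons, fmtNum)),
                as.data.frame(lapply(net@synapses, fmtNum)),
                as.data.frame(lapply(net@mu, fmtNum)))
  write.table(ntab, paste0(prefix, "_neurons.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  meta <- list(condition = net@condition, scaling = net@scaling,
               I_bg = net@I_bg, nonlinearity = net@nonlinearity,
               spines = net@spines, config = net@config, seed = net@seed,
               n = length(net@groupOf))
  jsonlite::write_json(meta, paste0(prefix, "_meta.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(prefix)
}

#' @rdname writeNetwork
#' @export
readNetwork <- function(prefix) {
  edges <- read.delim(paste0(prefix, "_edges.tsv"))
  ntab <- read.delim(paste0(prefix, "_neurons.tsv"))
  meta <- jsonlite::read_json(paste0(prefix, "_meta.json"),
                              simplifyVector = TRUE)
  n <- meta$n
  W <- matrix(0, n, n)
  if (nrow(edges)) W[cbind(edges$post, edges$pre)] <- edges$weight
  cfg <- meta$config
  cfg$p_connect <- as.list(cfg$p_connect)
  cfg$weights <- as.list(cfg$weights)
  methods::new("Network", groupOf = as.integer(ntab$group),
               isExc = as.logical(ntab$is_exc), W = W,
               neurons = ntab[.NEURON_FIELDS],
               synapses = ntab[.SYN_FIELDS],
               mu = ntab[c("mu_NMDA", "mu_AMPA", "mu_GABA")],
               spines = as.list(meta$spines),
               nonlinearity = as.list(meta$nonlinearity),
               scaling = as.list(meta$scaling), condition = meta$condition,
               I_bg = meta$I_bg, config = as.list(cfg),
               seed = as.integer(meta$seed))
}
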