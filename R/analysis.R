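#' @include AllClasses.R protocol.R params.R
NULL

#' Count the groups that sustain delay-period firing
#'
#' Working-memory capacity is the number of selective groups whose
#' excitatory population keeps discharging through the delay. A group counts
#' when at least \code{fraction_active} of its excitatory neurons fire above
#' \code{rate_threshold} Hz inside the criterion window (the last
#' \code{window} ms of the delay epoch). Deterministic; bounded above by the
#' number of structural groups.
#'
#' @param raster data.frame with \code{time_ms}, \code{neuron}.
#' @param groups A \code{neuronTable}-shaped data.frame (\code{neuron},
#'   \code{group}, \code{is_exc}) or an object with a \code{neuronTable}
#'   method.
#' @param proto The \code{\linkS4class{StimulusProtocol}} the raster was
#'   recorded under.
#' @param crit A \code{\link{capacityCriterion}}.
#' @return Integer capacity in [0, n_groups].
#' @export
workingMemoryCapacity <- function(raster, groups, proto,
                                  crit = capacityCriterion()) {
  if (!is.data.frame(groups)) groups <- neuronTable(groups)
  stopifnot(all(c("neuron", "group", "is_exc") %in% names(groups)),
            inherits(crit, "CapacityCriterion"))
  b <- epochBoundaries(proto)
  w1 <- b[["cue"]]                      # end of delay
  w0 <- max(b[["delay"]], w1 - crit$window)
  dur_s <- (w1 - w0) / 1000
  if (dur_s <= 0) stop("criterion window is empty", call. = FALSE)
  eg <- groups[groups$is_exc, ]
  if (any(table(factor(eg$group, levels = unique(groups$group))) == 0))
    stop("a group has no excitatory neurons", call. = FALSE)
  sel <- raster$time_ms >= w0 & raster$time_ms < w1
  cnt <- table(factor(raster$neuron[sel], levels = eg$neuron))
  rate <- as.numeric(cnt) / dur_s
  active <- rate >= crit$rate_threshold
  byGroup <- tapply(active, eg$group, mean)
  sum(byGroup >= crit$fraction_active)
}

#' Spike-count matrix
#'
#' Bins a raster into an integer count matrix, one row per unit and one
#' column per time window of \code{bin} ms across \code{span} ms starting at
#' \code{origin}.
#'
#' @param raster data.frame with \code{time_ms}, \code{neuron}.
#' @param neurons Integer ids of the units to include (rows, in order).
#' @param bin Window length (ms); must divide \code{span}.
#' @param span Total length (ms) binned.
#' @param origin Start time (ms) of the first window.
#' @return Integer matrix (units x windows) with attribute \code{bin_ms}.
#' @export
spikeCountMatrix <- function(raster, neurons, bin = 50, span = 5000,
                             origin = 0) {
  assertScalar(bin, "bin", positive = TRUE)
  assertScalar(span, "span", positive = TRUE)
  nW <- span / bin
  if (abs(nW - round(nW)) > 1e-9)
    stop("bin must divide span", call. = FALSE)
  nW <- as.integer(round(nW))
  sel <- raster$time_ms >= origin & raster$time_ms < origin + span &
    raster$neuron %in% neurons
  uid <- match(raster$neuron[sel], neurons)
  wid <- floor((raster$time_ms[sel] - origin) / bin) + 1L
  m <- matrix(0L, length(neurons), nW)
  if (length(uid)) {
    tab <- table(factor(uid, levels = seq_along(neurons)),
                 factor(wid, levels = seq_len(nW)))
    m <- matrix(as.integer(tab), length(neurons), nW)
  }
  dimnames(m) <- list(neurons, NULL)
  attr(m, "bin_ms") <- bin
  m
}

#' Intrinsic timescale from the spike-count autocorrelation
#'
#' Computes the lagged Pearson correlation of the spike-count series and
#' fits the exponential decay \eqn{\bar\rho(\Delta) = a\,(e^{-\Delta/\tau} +
#' b)} by Levenberg-Marquardt nonlinear least squares. Pooling across units:
#' by default each unit's lagged autocorrelations are computed separately
#' and averaged across units before fitting (robust for short spans); with
#' \code{pool = "population"} the columns are summed across units first and
#' a single series is correlated. Units with zero count variance are
#' dropped; if nothing usable remains the fit is flagged non-converged
#' rather than raising.
#'
#' @param counts Integer matrix (units x windows), e.g. from
#'   \code{\link{spikeCountMatrix}}; needs a \code{bin_ms} attribute or an
#'   explicit \code{bin}.
#' @param max_lag_windows Largest lag (in windows) entering the fit.
#' @param bin Window length (ms), overriding the attribute.
#' @param pool "units" (average per-unit correlations) or "population"
#'   (correlate the pooled series).
#' @return A list of class \code{"TimescaleFit"}: \code{tau} (ms),
#'   \code{a}, \code{b}, \code{lags_ms}, \code{rho}, \code{converged},
#'   \code{resid_norm}, \code{n_units_used}.
#' @export
autocorrelationTimescale <- function(counts, max_lag_windows = 20,
                                     bin = attr(counts, "bin_ms"),
                                     pool = c("units", "population")) {
  pool <- match.arg(pool)
  if (is.null(bin)) stop("bin width unknown; pass 'bin'", call. = FALSE)
  if (!is.matrix(counts)) counts <- matrix(counts, nrow = 1)
  nW <- ncol(counts)
  maxLag <- min(max_lag_windows, nW - 3L)
  if (maxLag < 3L)
    stop("need at least 3 usable lags", call. = FALSE)
  lagRho <- function(xs) {
    vapply(seq_len(maxLag), function(L) {
      a <- xs[seq_len(nW - L)]
      b <- xs[seq_len(nW - L) + L]
      if (stats::sd(a) == 0 || stats::sd(b) == 0) return(NA_real_)
      cor(a, b)
    }, numeric(1))
  }
  if (pool == "population") {
    rho <- lagRho(colSums(counts))
    nUsed <- nrow(counts)
  } else {
    keep <- apply(counts, 1, function(r) stats::sd(r) > 0)
    nUsed <- sum(keep)
    if (nUsed == 0) {
      return(structure(list(tau = NA_real_, a = NA_real_, b = NA_real_,
                            lags_ms = seq_len(maxLag) * bin,
                            rho = rep(NA_real_, maxLag), converged = FALSE,
                            resid_norm = NA_real_, n_units_used = 0L),
                       class = "TimescaleFit"))
    }
    rmat <- t(apply(counts[keep, , drop = FALSE], 1, lagRho))
    if (maxLag == 1L) rmat <- t(rmat)
    rho <- colMeans(rmat, na.rm = TRUE)
  }
  fitTimescaleCurve(seq_len(maxLag) * bin, rho, bin, nUsed)
}

# Shared LM fit of rho(Delta) = a (exp(-Delta/tau) + b).
fitTimescaleCurve <- function(lags_ms, rho, bin, n_units_used = NA_integer_) {
  ok <- is.finite(rho)
  out <- structure(list(tau = NA_real_, a = NA_real_, b = NA_real_,
                        lags_ms = lags_ms, rho = rho, converged = FALSE,
                        resid_norm = NA_real_,
                        n_units_used = n_units_used),
                   class = "TimescaleFit")
  if (sum(ok) < 3) return(out)
  df <- data.frame(lag = lags_ms[ok], rho = rho[ok])
  fit <- tryCatch(
    minpack.lm::nlsLM(rho ~ a * (exp(-lag / tau) + b), data = df,
                      start = list(a = 1, b = 0, tau = 2 * bin),
                      lower = c(a = -Inf, b = -Inf, tau = 1e-6),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (is.null(fit)) return(out)
  cf <- coef(fit)
  out$tau <- unname(cf["tau"])
  out$a <- unname(cf["a"])
  out$b <- unname(cf["b"])
  out$resid_norm <- sqrt(sum(stats::resid(fit)^2))
  # a decaying component must actually be present: with amplitude near zero
  # (e.g. white-noise counts) tau is unidentifiable, so the fit is flagged
  out$converged <- isTRUE(fit$convInfo$isConv) && out$tau > 0 &&
    abs(out$a) > 0.05
  out
}

#' Fit the timescale curve to given correlation values
#'
#' Direct access to the exponential-decay fitter, for correlation curves
#' computed elsewhere.
#'
#' @param lags_ms Lag values (ms).
#' @param rho Correlation at each lag.
#' @param bin Window length (ms), used for the initialization tau = 2 bins.
#' @return A \code{"TimescaleFit"} list; see
#'   \code{\link{autocorrelationTimescale}}.
#' @export
fitTimescale <- function(lags_ms, rho, bin = diff(lags_ms[1:2])) {
  fitTimescaleCurve(lags_ms, rho, bin)
}

#' Epoch-anchored intrinsic timescales
#'
#' Runs the spike-count autocorrelation pipeline on count matrices anchored
#' at the start of the memory epoch and at the start of the cue epoch,
#' separately for the excitatory and inhibitory populations. A cue-epoch
#' timescale above the memory-epoch one indicates improved maintenance
#' after the probe.
#'
#' @param result A \code{\linkS4class{SimulationResult}}.
#' @param epochs Epoch names to anchor at (subset of the protocol epochs).
#' @param bin Window length (ms).
#' @param max_lag_windows Largest lag (windows) entering each fit.
#' @param restrict_to_groups Optional integer group ids; default pools all
#'   neurons of each population.
#' @return Nested list \code{result[[epoch]][[population]]} of
#'   \code{"TimescaleFit"} objects.
#' @export
epochTimescales <- function(result, epochs = c("memory", "cue"), bin = 50,
                            max_lag_windows = 20,
                            restrict_to_groups = NULL) {
  stopifnot(is(result, "SimulationResult"))
  b <- epochBoundaries(result@protocol)
  nt <- neuronTable(result)
  if (!is.null(restrict_to_groups))
    nt <- nt[nt$group %in% restrict_to_groups, ]
  raster <- result@raster
  out <- list()
  for (ep in epochs) {
    if (!ep %in% names(b)) stop("unknown epoch: ", ep, call. = FALSE)
    origin <- b[[ep]]
    avail <- result@span - origin
    nW <- floor(avail / bin)
    if (nW < 6)
      stop(sprintf("epoch '%s' leaves %d windows; need >= 6 for >= 3 lags",
                   ep, nW), call. = FALSE)
    span <- nW * bin
    out[[ep]] <- lapply(list(E = nt$neuron[nt$is_exc],
                             I = nt$neuron[!nt$is_exc]), function(ids) {
      m <- spikeCountMatrix(raster, ids, bin = bin, span = span,
                            origin = origin)
      autocorrelationTimescale(m, max_lag_windows = max_lag_windows,
                               bin = bin)
    })
  }
  out
}

#' Correlation between a sweep axis and an outcome
#'
#' Pearson correlation (with two-sided p value) between the swept axis
#' values and an outcome column of a sweep table, mirroring the
#' capacity-vs-current-strength correlation tables of the sweep analyses.
#'
#' @param table Sweep result data.frame.
#' @param axis Axis column name.
#' @param outcome Outcome column name (default "capacity").
#' @return List with \code{r}, \code{p}, \code{n}; \code{r} is \code{NA}
#'   with a note when the outcome is constant.
#' @export
sweepCorrelation <- function(table, axis, outcome = "capacity") {
  stopifnot(axis %in% names(table), outcome %in% names(table))
  ok <- is.finite(table[[axis]]) & is.finite(table[[outcome]])
  x <- table[[axis]][ok]; y <- table[[outcome]][ok]
  if (length(x) < 3) stop("need >= 3 points", call. = FALSE)
  if (stats::sd(y) == 0 || stats::sd(x) == 0)
    return(list(r = NA_real_, p = NA_real_, n = length(x),
                note = "constant variable; correlation undefined"))
  ct <- cor.test(x, y)
  list(r = unname(ct$estimate), p = ct$p.value, n = length(x))
}

#' Mean current trace of a population
#'
#' Per-time-point mean over the population for one receptor. Uses the
#' per-neuron current arrays when the run recorded them (so arbitrary
#' subpopulations work), falling back to the stored population means.
#'
#' @param result A \code{\linkS4class{SimulationResult}}.
#' @param population "E" or "I".
#' @param receptor One of "AMPA_ext", "AMPA_rec", "NMDA", "GABA".
#' @return data.frame with \code{time_ms}, \code{value}.
#' @export
meanCurrentTraces <- function(result, population = c("E", "I"),
                              receptor = c("NMDA", "AMPA_rec", "AMPA_ext",
                                           "GABA")) {
  stopifnot(is(result, "SimulationResult"))
  population <- match.arg(population)
  receptor <- match.arg(receptor)
  if (!is.null(result@neuronCurrents)) {
    m <- result@neuronCurrents[[receptor]]
    if (is.null(m)) stop("receptor not recorded: ", receptor, call. = FALSE)
    ids <- if (population == "E") which(result@isExc) else
      which(!result@isExc)
    if (!length(ids)) stop("empty population: ", population, call. = FALSE)
    return(data.frame(time_ms = attr(result@neuronCurrents, "time_ms"),
                      value = rowMeans(m[, ids, drop = FALSE])))
  }
  cu <- result@currents
  sel <- cu$population == population & cu$receptor == receptor
  if (!any(sel)) stop("receptor not recorded: ", receptor, call. = FALSE)
  data.frame(time_ms = cu$time_ms[sel], value = cu$value[sel])
}
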