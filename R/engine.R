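#' @include AllClasses.R dynamics.R network.R protocol.R stress.R
NULL

#' Run one simulation of the recall protocol
#'
#' Integrates the full network with fixed-step forward Euler. Each step:
#' (1) external AMPA gating of excitatory neurons is driven by per-step
#' Poisson input counts at the protocol's epoch rate; (2) recurrent gating
#' and short-term plasticity advance from the previous step's spikes (one
#' time step of synaptic delay); (3) the NMDA, AMPA, GABA, dendritic and
#' background currents are evaluated and combined with the condition's
#' scaling factors; (4) membranes step, spikes are recorded exactly, and at
#' the recording stride the population mean current magnitudes are stored.
#' Fully deterministic given the seed.
#'
#' @param net A \code{\linkS4class{Network}} (control or pre-transformed).
#' @param proto A \code{\linkS4class{StimulusProtocol}}.
#' @param cond A \code{\linkS4class{StressCondition}} applied before the
#'   run; defaults to control (identity).
#' @param dt Integration step (ms).
#' @param seed Integer seed for the input stream.
#' @param record_stride Current-recording stride (ms); recording is passive
#'   and never alters the dynamics.
#' @param record_neuron_currents Keep per-neuron current arrays (memory
#'   heavy; needed only for neuron-resolved current analyses).
#' @param transfer Dendrite-to-soma transfer strategy, a function
#'   \code{(I_exc, I_inh, nl) -> pA}; defaults to
#'   \code{\link{dendriteToSoma}}.
#' @return A \code{\linkS4class{SimulationResult}}.
#' @export
runSimulation <- function(net, proto, cond = stressCondition("control"),
                          dt = 0.05, seed = 1, record_stride = 1,
                          record_neuron_currents = FALSE,
                          transfer = dendriteToSoma) {
  stopifnot(is(net, "Network"), is(proto, "StimulusProtocol"))
  assertScalar(dt, "dt", positive = TRUE)
  # plain BLAS matrix products: the default NaN pre-scan would dominate the
  # step cost; non-finite states are caught by the explicit check below
  oldmp <- options(matprod = "blas")
  on.exit(options(oldmp), add = TRUE)
  net <- applyCondition(net, cond)
  n <- length(net@groupOf)
  isExc <- net@isExc
  exc <- which(isExc); inh <- which(!isExc)
  nE <- length(exc); nI <- length(inh)

  span <- protocolSpan(proto)
  nSteps <- ceiling(span / dt)
  strideSteps <- max(1L, round(record_stride / dt))

  # per-neuron membrane constants
  nr <- net@neurons
  sy <- net@synapses
  mu <- net@mu
  W_E <- net@W[, exc, drop = FALSE]
  W_I <- net@W[, inh, drop = FALSE]
  scal <- do.call(stressScaling, net@scaling)
  nl <- do.call(dendriteNonlinearity, net@nonlinearity)
  defaultTransfer <- identical(transfer, dendriteToSoma)
  c1 <- nl$c1; c2 <- nl$c2; c3 <- nl$c3; c4 <- nl$c4; c5 <- nl$c5
  c6 <- nl$c6

  # presynaptic STP/gating parameter vectors
  tauA_E <- sy$tau_AMPA[exc]; tauN_E <- sy$tau_NMDA[exc]
  tauG_I <- sy$tau_GABA[inh]
  U_E <- sy$U[exc]; tau_u_E <- sy$tau_u[exc]; tau_x_E <- sy$tau_x[exc]
  gA_E <- sy$gamma_AMPA[exc]; gN_E <- sy$gamma_NMDA[exc]
  gI_I <- sy$gamma_I[inh]
  decA <- exp(-dt / tauA_E); decN <- exp(-dt / tauN_E)
  decG <- exp(-dt / tauG_I)
  decU <- exp(-dt / tau_u_E); decX <- exp(-dt / tau_x_E)
  decExt <- exp(-dt / sy$tau_AMPA)   # external gating decays per target

  # postsynaptic factors
  muN_g <- mu$mu_NMDA * sy$g_NMDA_rec
  muA_g <- mu$mu_AMPA * sy$g_AMPA_rec
  muG_g <- mu$mu_GABA * sy$g_GABA
  gExt <- sy$g_AMPA_ext
  gammaMg <- sy$gamma_mg; betaMg <- sy$beta_mg
  betaN <- scal$beta_NMDA; betaA <- scal$beta_AMPA

  # hoisted per-neuron constants
  C_m <- nr$C_m; g_L <- nr$g_L; V_L <- nr$V_L; V_th <- nr$V_th
  V_reset <- nr$V_reset; t_ref <- nr$t_ref
  I_bg <- net@I_bg
  zeroN <- numeric(n)

  # state
  V <- nr$V_L
  refrUntil <- rep(-Inf, n)
  spiked <- logical(n)
  sA <- numeric(nE); sN <- numeric(nE); sG <- numeric(nI)
  u <- U_E; x <- rep(1, nE)
  sExt <- numeric(n)

  # per-step external input rates (Hz -> expected count per target per step)
  stepT <- (seq_len(nSteps) - 1) * dt
  lambda <- protocolRate(stepT, proto) * dt / 1000

  nRec <- length(seq(1L, nSteps, by = strideSteps))
  recT <- numeric(nRec)
  recMeans <- array(0, dim = c(nRec, 2L, 4L),
                    dimnames = list(NULL, c("E", "I"),
                                    c("AMPA_ext", "AMPA_rec", "NMDA",
                                      "GABA")))
  nrnCur <- NULL
  if (record_neuron_currents)
    nrnCur <- list(AMPA_ext = matrix(0, nRec, n),
                   AMPA_rec = matrix(0, nRec, n),
                   NMDA = matrix(0, nRec, n), GABA = matrix(0, nRec, n))

  spkT <- vector("list", 256L); spkN <- vector("list", 256L); nspk <- 0L

  cfg <- list(network = net@config, condition = net@condition,
              scaling = net@scaling,
              protocol = list(t_fixation = proto@t_fixation,
                              t_memory = proto@t_memory,
                              t_delay = proto@t_delay, t_cue = proto@t_cue,
                              t_post = proto@t_post,
                              rate_memory = proto@rate_memory,
                              rate_cue = proto@rate_cue,
                              rate_background = proto@rate_background),
              dt = dt, record_stride = record_stride)
  hash <- configHash(cfg)

  set.seed(streamSeed(seed, "inputs"))
  recI <- 0L
  for (k in seq_len(nSteps)) {
    t <- stepT[k]
    # (1) external Poisson drive onto excitatory targets
    sExt <- sExt * decExt
    if (lambda[k] > 0)
      sExt[exc] <- sExt[exc] + rpois(nE, lambda[k])
    # (2) gating + STP driven by last step's spikes (one-step delay)
    sA <- sA * decA; sN <- sN * decN; sG <- sG * decG
    u <- U_E + (u - U_E) * decU
    x <- 1 + (x - 1) * decX
    spkE <- spiked[exc]
    if (any(spkE)) {
      u2 <- u[spkE] + U_E[spkE] * (1 - u[spkE])
      inc <- x[spkE] * u2
      sA[spkE] <- sA[spkE] + inc * gA_E[spkE]
      sN[spkE] <- sN[spkE] + inc * (1 - sN[spkE]) * gN_E[spkE]
      x[spkE] <- x[spkE] - inc
      u[spkE] <- u2
    }
    spkI <- spiked[inh]
    if (any(spkI)) sG[spkI] <- sG[spkI] + gI_I[spkI]
    anyActiveE <- max(sA) > 1e-12 || max(sN) > 1e-12
    anyActiveI <- max(sG) > 1e-12
    # (3) currents (depolarizing magnitudes; vanish at V = V_L)
    if (anyActiveE) {
      D <- W_E %*% cbind(sN * u, sA * u)
      driveN <- D[, 1L]; driveA <- D[, 2L]
    } else {
      driveN <- driveA <- zeroN
    }
    driveG <- if (anyActiveI) as.numeric(W_I %*% sG) else zeroN
    dv <- V - V_L
    mg <- 1 / (1 + gammaMg * exp(-betaMg * V))
    I_N <- muN_g * mg * dv * driveN
    I_Ar <- muA_g * dv * driveA
    I_Ax <- gExt * dv * sExt
    I_G <- muG_g * dv * driveG
    I_exc_dend <- I_N + I_Ax + I_Ar + I_bg
    I_sd <- if (defaultTransfer) {
      c1 * tanh((I_exc_dend + c3 * I_G + c4) / (c5 * exp(-I_G / c6))) + c2
    } else transfer(I_exc_dend, I_G, nl)
    I_tot <- betaN * I_N + I_Ax + betaA * I_Ar - I_G + I_sd + I_bg
    # (4) membrane update
    Vn <- V + dt * (-g_L * (V - V_L) + I_tot) / C_m
    if (anyNA(Vn) || any(!is.finite(Vn))) {
      bad <- which(!is.finite(Vn))[1]
      stop(sprintf(
        "numerical blow-up at step %d (t = %g ms), neuron %d, V = %g",
        k, t, bad, V[bad]), call. = FALSE)
    }
    refr <- t < refrUntil
    if (any(refr)) Vn[refr] <- V_reset[refr]
    spiked <- (Vn >= V_th) & !refr
    if (any(spiked)) {
      Vn[spiked] <- V_reset[spiked]
      refrUntil[spiked] <- t + t_ref[spiked]
      nspk <- nspk + 1L
      if (nspk > length(spkT)) {
        length(spkT) <- 2L * length(spkT); length(spkN) <- length(spkT)
      }
      ids <- which(spiked)
      spkT[[nspk]] <- rep(t + dt, length(ids))
      spkN[[nspk]] <- ids
    }
    V <- Vn
    # recording (passive)
    if ((k - 1L) %% strideSteps == 0L) {
      recI <- recI + 1L
      recT[recI] <- t
      recMeans[recI, "E", ] <- c(mean(I_Ax[exc]), mean(I_Ar[exc]),
                                 mean(I_N[exc]), mean(I_G[exc]))
      recMeans[recI, "I", ] <- c(mean(I_Ax[inh]), mean(I_Ar[inh]),
                                 mean(I_N[inh]), mean(I_G[inh]))
      if (record_neuron_currents) {
        nrnCur$AMPA_ext[recI, ] <- I_Ax
        nrnCur$AMPA_rec[recI, ] <- I_Ar
        nrnCur$NMDA[recI, ] <- I_N
        nrnCur$GABA[recI, ] <- I_G
      }
    }
  }

  raster <- if (nspk > 0) {
    data.frame(time_ms = unlist(spkT[seq_len(nspk)]),
               neuron = unlist(spkN[seq_len(nspk)]))
  } else data.frame(time_ms = numeric(0), neuron = integer(0))
  # spike times are stamped at the end of the crossing step
  raster$time_ms <- pmin(raster$time_ms, span)

  recT <- recT[seq_len(recI)]
  cur <- expand.grid(time_ms = recT, population = c("E", "I"),
                     receptor = c("AMPA_ext", "AMPA_rec", "NMDA", "GABA"),
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  cur$value <- as.numeric(recMeans[seq_len(recI), , ])
  if (record_neuron_currents) {
    nrnCur <- lapply(nrnCur, function(m) {
      m <- m[seq_len(recI), , drop = FALSE]; rownames(m) <- NULL; m
    })
    attr(nrnCur, "time_ms") <- recT
  }

  methods::new("SimulationResult", raster = raster, currents = cur,
               neuronCurrents = nrnCur, protocol = proto,
               condition = net@condition, groupOf = net@groupOf,
               isExc = isExc, dt = dt, span = span,
               seed = as.integer(seed), configHash = hash)
}

#' Run a parameter sweep
#'
#' Reruns the full protocol for every grid point and replicate. All points
#' share the network realization built from \code{build_seed} (isolating the
#' swept factor); replicates differ only in the input-noise seed. Rows that
#' fail are recorded with an error message and the sweep continues. If
#' \code{out_tsv} is given, rows are appended as they finish and an
#' interrupted sweep resumes past the completed rows.
#'
#' @param net A \code{\linkS4class{Network}} (shared realization), already
#'   in its base condition.
#' @param proto A \code{\linkS4class{StimulusProtocol}}.
#' @param grid A \code{\link{sweepGrid}}.
#' @param cond Base \code{\linkS4class{StressCondition}} applied before the
#'   axes.
#' @param dt Integration step (ms).
#' @param seed Master seed; replicate r uses input seed \code{seed + r}.
#' @param criterion \code{\link{capacityCriterion}} for the capacity column.
#' @param timescales Also fit epoch timescales per row (slower).
#' @param out_tsv Optional path for incremental tab-separated output.
#' @param verbose Log progress via \code{message()}.
#' @return data.frame: one row per grid point x replicate with the axis
#'   values, replicate, seed, capacity, mean delay-epoch current magnitudes
#'   (pA; E population), optional timescale columns, and an error column.
#' @export
runSweep <- function(net, proto, grid, cond = stressCondition("control"),
                     dt = 0.05, seed = 1,
                     criterion = capacityCriterion(), timescales = FALSE,
                     out_tsv = NULL, verbose = TRUE) {
  stopifnot(is(net, "Network"), inherits(grid, "SweepGrid"))
  base <- applyCondition(net, cond)
  pts <- grid$points
  axes <- names(grid$axes)
  done <- NULL
  if (!is.null(out_tsv) && file.exists(out_tsv)) {
    done <- read.delim(out_tsv)
    if (verbose) message(sprintf("resuming: %d rows already done",
                                 nrow(done)))
  }
  rows <- vector("list", nrow(pts) * grid$replicates)
  ri <- 0L
  for (i in seq_len(nrow(pts))) {
    netp <- base
    for (ax in axes) netp <- applySweepAxis(netp, ax, pts[i, ax])
    for (r in seq_len(grid$replicates)) {
      ri <- ri + 1L
      if (!is.null(done) && nrow(done) >= ri) { rows[[ri]] <- done[ri, ]; next }
      row <- cbind(pts[i, , drop = FALSE],
                   data.frame(replicate = r, seed = seed + r,
                              capacity = NA_real_, I_AMPA_rec = NA_real_,
                              I_NMDA = NA_real_, I_GABA = NA_real_,
                              error = NA_character_))
      if (timescales)
        row <- cbind(row, data.frame(tau_E_memory = NA_real_,
                                     tau_I_memory = NA_real_,
                                     tau_E_cue = NA_real_,
                                     tau_I_cue = NA_real_))
      res <- tryCatch(
        runSimulation(netp, proto, dt = dt, seed = seed + r),
        error = function(e) e)
      if (inherits(res, "error")) {
        row$error <- conditionMessage(res)
      } else {
        row$capacity <- workingMemoryCapacity(
          spikeRaster(res), neuronTable(res), proto, criterion)
        dl <- delayMeanCurrents(res)
        row$I_AMPA_rec <- dl[["AMPA_rec"]]
        row$I_NMDA <- dl[["NMDA"]]
        row$I_GABA <- dl[["GABA"]]
        if (timescales) {
          ts <- tryCatch(epochTimescales(res), error = function(e) NULL)
          if (!is.null(ts)) {
            row$tau_E_memory <- ts$memory$E$tau
            row$tau_I_memory <- ts$memory$I$tau
            row$tau_E_cue <- ts$cue$E$tau
            row$tau_I_cue <- ts$cue$I$tau
          }
        }
      }
      rownames(row) <- NULL
      rows[[ri]] <- row
      if (!is.null(out_tsv))
        suppressWarnings(write.table(row, out_tsv, sep = "\t",
                                     quote = FALSE, row.names = FALSE,
                                     col.names = !file.exists(out_tsv),
                                     append = file.exists(out_tsv)))
      if (verbose)
        message(sprintf("sweep %d/%d: %s -> capacity %s",
                        ri, nrow(pts) * grid$replicates,
                        paste(sprintf("%s=%g", axes,
                                      unlist(pts[i, axes])),
                              collapse = ", "),
                        format(row$capacity)))
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# Mean current magnitudes of the E population during the delay epoch.
delayMeanCurrents <- function(result) {
  b <- epochBoundaries(result@protocol)
  cu <- result@currents
  sel <- cu$population == "E" & cu$time_ms >= b[["delay"]] &
    cu$time_ms < b[["cue"]]
  vapply(split(abs(cu$value[sel]), cu$receptor[sel]), mean, numeric(1))
}

# ---- raster / trace file formats ------------------------------------------

#' Write / read a spike raster as plain text
#'
#' Two tab-separated columns \code{time_ms}, \code{neuron}, preceded by
#' \code{# key: value} metadata header lines (at least \code{span_ms}; plus
#' group/type tables when a \code{neuronTable} is supplied). Round-trips
#' exactly.
#'
#' @param raster data.frame with \code{time_ms}, \code{neuron}.
#' @param path Output file.
#' @param meta Named list of scalar metadata.
#' @param neurons Optional \code{neuronTable}-shaped data.frame stored in
#'   the header so capacity analysis can run from the file alone.
#' @return \code{writeRaster}: the path, invisibly. \code{readRaster}: the
#'   raster data.frame with metadata in attributes (\code{meta},
#'   \code{neurons}).
#' @export
writeRaster <- function(raster, path, meta = list(), neurons = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  for (nm in names(meta))
    writeLines(sprintf("# %s: %s", nm, format(meta[[nm]], digits = 17)), con)
  if (!is.null(neurons)) {
    writeLines(sprintf("# neurons: %s", paste(
      sprintf("%d,%d,%d", neurons$neuron, neurons$group,
              as.integer(neurons$is_exc)), collapse = ";")), con)
  }
  writeLines("time_ms\tneuron", con)
  if (nrow(raster))
    writeLines(sprintf("%s\t%d", fmtNum(raster$time_ms),
                       as.integer(raster$neuron)), con)
  invisible(path)
}

#' @rdname writeRaster
#' @export
readRaster <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#", lines)
  meta <- list(); neurons <- NULL
  for (h in hdr) {
    kv <- sub("^# *", "", lines[h])
    key <- sub(":.*$", "", kv)
    val <- sub("^[^:]*: *", "", kv)
    if (key == "neurons") {
      parts <- strsplit(strsplit(val, ";")[[1]], ",")
      m <- do.call(rbind, lapply(parts, as.integer))
      neurons <- data.frame(neuron = m[, 1], group = m[, 2],
                            is_exc = as.logical(m[, 3]))
    } else {
      num <- suppressWarnings(as.numeric(val))
      meta[[key]] <- if (is.na(num)) val else num
    }
  }
  body <- lines[setdiff(seq_along(lines), hdr)]
  if (length(body) > 1) {
    df <- read.delim(text = body)
  } else {
    df <- data.frame(time_ms = numeric(0), neuron = integer(0))
  }
  attr(df, "meta") <- meta
  attr(df, "neurons") <- neurons
  df
}

#' Write / read current traces as tidy columnar text
#'
#' Columns \code{time_ms}, \code{population}, \code{receptor},
#' \code{value}; full-precision, exact round trip.
#'
#' @param traces data.frame as stored in a result's \code{currents} slot.
#' @param path File path.
#' @return \code{writeTraces}: path invisibly; \code{readTraces}: the
#'   data.frame.
#' @export
writeTraces <- function(traces, path) {
  out <- traces
  out$time_ms <- fmtNum(out$time_ms)
  out$value <- fmtNum(out$value)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writeTraces
#' @export
readTraces <- function(path) {
  read.delim(path, colClasses = c("numeric", "character", "character",
                                  "numeric"))
}
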