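#' @import methods
#' @importFrom stats rpois rnorm runif cor cor.test coef nls.control
#' @importFrom utils modifyList read.delim write.table head tail
NULL

# Derived RNG stream seeds. R has no independent named streams, so sub-stage
# seeds are deterministic functions of the master seed, kept in 32-bit range.
.STREAMS <- c(connectivity = 1L, heterogeneity = 2L, inputs = 3L, fixtures = 4L)

streamSeed <- function(seed, stream) {
  stopifnot(stream %in% names(.STREAMS))
  off <- .STREAMS[[stream]]
  as.integer((as.numeric(seed) * 48271 + off * 16807) %% 2147483647)
}

withStream <- function(seed, stream, expr) {
  set.seed(streamSeed(seed, stream))
  expr
}

# Truncated-Gaussian draw with a positive floor, for heterogeneous parameter
# assignment. Redraws (not clips) so the distribution stays smooth.
rtruncnorm <- function(n, mean, sd, lower = .Machine$double.eps) {
  x <- rnorm(n, mean, sd)
  bad <- which(x <= lower)
  tries <- 0L
  while (length(bad) > 0L && tries < 100L) {
    x[bad] <- rnorm(length(bad), mean, sd)
    bad <- bad[x[bad] <= lower]
    tries <- tries + 1L
  }
  if (length(bad) > 0L) x[bad] <- lower
  x
}

assertScalar <- function(x, name, positive = FALSE, nonneg = FALSE,
                         finite = TRUE) {
  if (!is.numeric(x) || length(x) != 1L || (finite && !is.finite(x)))
    stop(sprintf("'%s' must be a finite numeric scalar", name), call. = FALSE)
  if (positive && x <= 0)
    stop(sprintf("'%s' must be > 0", name), call. = FALSE)
  if (nonneg && x < 0)
    stop(sprintf("'%s' must be >= 0", name), call. = FALSE)
  invisible(x)
}

assertFraction <- function(x, name) {
  assertScalar(x, name)
  if (x < 0 || x > 1)
    stop(sprintf("'%s' must lie in [0, 1]", name), call. = FALSE)
  invisible(x)
}

# Full-precision number formatting so text round-trips are exact.
fmtNum <- function(x) sprintf("%.17g", x)

#' Hash of an R configuration object
#'
#' Canonical md5 of the JSON serialization; used to stamp simulation
#' outputs so a result can be traced back to the exact configuration.
#'
#' @param x A list-like configuration object.
#' @return A length-1 character md5 string.
#' @export
configHash <- function(x) {
  f <- tempfile(fileext = ".json")
  on.exit(unlink(f), add = TRUE)
  jsonlite::write_json(x, f, auto_unbox = TRUE, digits = NA, force = TRUE)
  unname(tools::md5sum(f))
}
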