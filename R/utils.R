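#' Derive a named substream seed from a master seed
#'
#' All randomness in a multi-stage run (simulation, MCMC, fold assignment)
#' flows from one master seed fanned out to named substreams, so that stages
#' can be re-run independently yet reproducibly.
#'
#' @param seed master seed, a single integer.
#' @param name character label of the substream, e.g. `"mcmc"` or `"cv"`.
#' @return an integer seed in `[0, 2^31)`, deterministic in `(seed, name)`.
#' @examples
#' substream_seed(1, "cv")
#' @export
substream_seed <- function(seed, name) {
  stopifnot(length(seed) == 1L, is.finite(seed), is.character(name))
  # FNV-1a style hash over the seed digits and the stream name, kept in
  # double precision below 2^31 (R integers are 32-bit)
  h <- 2166136261
  for (b in utf8ToInt(paste0(format(seed, scientific = FALSE), ":", name))) {
    h <- (bitwXor(as.integer(h %% 2^31), b) * 16777619) %% 2^31
  }
  as.integer(h %% .Machine$integer.max)
}

#' @keywords internal
`%||%` <- function(a, b) if (is.null(a)) b else a

# symmetry check used by relationship-matrix constructors
check_symmetric <- function(m, tol = 1e-10, what = "matrix") {
  if (nrow(m) != ncol(m) || max(abs(m - t(m))) > tol) {
    stop(sprintf("%s is not symmetric within %g", what, tol), call. = FALSE)
  }
  invisible(TRUE)
}

# tiny stable hash of an R object, used for run logs
config_hash <- function(x) {
  s <- paste(deparse(x), collapse = "")
  h <- 2166136261
  for (b in utf8ToInt(s)) h <- (bitwXor(as.integer(h %% 2^31), b) * 16777619) %% 2^31
  sprintf("%08x", as.integer(h %% .Machine$integer.max))
}
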