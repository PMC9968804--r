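# Helpers: seed substreams and stage-prefixed logging.

#' Derive a per-stage seed from a single run seed
#'
#' Every pipeline stage (and every embedding restart) seeds its own random
#' substream from the master seed and a fixed integer offset, so stages can be
#' rerun individually and still reproduce the full-run results. The value is
#' kept below 2^31 - 1 so it is always a valid R integer.
#'
#' @param seed master integer seed.
#' @param offset integer substream offset (each consumer uses a fixed one).
#' @return An integer seed.
#' @export
substream_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) %% 100000L) * 7919 + offset * 104729) %% 2147483647L
}

#' @noRd
mir3d_log <- function(stage, ..., level = "INFO") {
  if (isTRUE(getOption("mir3d.quiet", FALSE))) return(invisible(NULL))
  message(format(Sys.time(), "%H:%M:%S"), " [", level, "] ", stage, ": ", ...)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_config <- function(...) stop("invalid configuration: ", ..., call. = FALSE)

# uniform points in a ball of given radius
runif_ball <- function(n, radius) {
  u <- matrix(rnorm(n * 3), ncol = 3)
  u <- u / sqrt(rowSums(u^2))
  u * radius * runif(n)^(1 / 3)
}
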