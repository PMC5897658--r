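#' Uniformly sampled current trace
#'
#' The package-wide container for whole-cell, synaptic-like, and
#' single-channel current records. Currents follow the physiological sign
#' convention: inward currents are negative.
#'
#' @param time time vector, s (uniform, strictly increasing)
#' @param current current vector, pA (same length as `time`)
#' @param sampling_rate sampling rate, Hz; inferred from `time` when NULL
#' @param protocol optional [application_protocol()]
#' @param holding_potential holding potential, mV
#' @param cell_id,construct optional identification strings
#' @return object of class `current_trace`
#' @export
current_trace <- function(time, current, sampling_rate = NULL, protocol = NULL,
                          holding_potential = -60, cell_id = NA_character_,
                          construct = NA_character_) {
  if (length(time) != length(current)) {
    stop("time and current must have the same length", call. = FALSE)
  }
  if (length(time) < 2L) stop("trace must contain at least two samples", call. = FALSE)
  dt <- diff(time)
  if (any(dt <= 0)) stop("time must be strictly increasing", call. = FALSE)
  if (max(abs(dt - dt[1])) > 1e-9 * dt[1] + 1e-15) {
    stop("time must be uniformly sampled", call. = FALSE)
  }
  fs <- 1 / dt[1]
  if (!is.null(sampling_rate) && abs(sampling_rate - fs) > 1e-6 * fs) {
    stop(sprintf("declared sampling_rate (%g Hz) inconsistent with time column (%g Hz)",
                 sampling_rate, fs), call. = FALSE)
  }
  if (!is.null(protocol)) stopifnot(is_protocol(protocol))
  structure(list(time = time, current = current, sampling_rate = fs,
                 protocol = protocol, holding_potential = holding_potential,
                 cell_id = cell_id, construct = construct),
            class = "current_trace")
}

#' @export
print.current_trace <- function(x, ...) {
  cat(sprintf("<current_trace>  %d samples @ %g kHz, %.3g s, Vh = %g mV\n",
              length(x$time), x$sampling_rate / 1000,
              diff(range(x$time)), x$holding_potential))
  if (!is.na(x$cell_id)) cat("  cell:", x$cell_id, "\n")
  if (!is.na(x$construct)) cat("  construct:", x$construct, "\n")
  if (!is.null(x$protocol)) cat(sprintf("  protocol: %d epoch(s)\n", nrow(x$protocol$epochs)))
  invisible(x)
}

is_current_trace <- function(x) inherits(x, "current_trace")

#' Ground truth attached to a synthetic trace
#'
#' Generators attach the parameters they were run with, so every estimator
#' test can close the loop against known truth.
#'
#' @param trace a [current_trace()]
#' @return the ground-truth list, or NULL for measured data
#' @export
ground_truth <- function(trace) attr(trace, "ground_truth")

#' Gaussian white-noise specification for the generators
#'
#' @param sd noise standard deviation, pA (>= 0)
#' @param seed integer seed; NULL leaves the RNG state alone
#' @return object of class `noise_spec`
#' @export
noise_spec <- function(sd = 0, seed = NULL) {
  if (!is.numeric(sd) || length(sd) != 1L || sd < 0) {
    stop("noise sd must be a single number >= 0", call. = FALSE)
  }
  structure(list(sd = sd, seed = seed), class = "noise_spec")
}

# Evaluate expr with a locally seeded RNG, restoring the caller's state.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    set.seed(NULL)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  expr
}
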