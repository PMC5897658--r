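# Single-channel analysis: Bessel-type low-pass filtering, half-amplitude
# idealization with dead-time censoring, single-Gaussian amplitude analysis,
# and time-averaged open probability.

# Poles of the analog Bessel low-pass prototype, normalized so the -3 dB
# point sits at 1 rad/s. Computed from the reverse Bessel polynomial
# theta_n(s) with coefficients (2n-k)! / (2^(n-k) k! (n-k)!).
bessel_poles <- function(order) {
  k <- 0:order
  coefs <- factorial(2 * order - k) /
    (2^(order - k) * factorial(k) * factorial(order - k))
  poles <- polyroot(coefs)           # ascending powers
  a0 <- coefs[1]
  mag2 <- function(w) {
    s <- complex(real = 0, imaginary = w)
    Mod(sum(coefs * s^k))^2
  }
  w3 <- stats::uniroot(function(w) mag2(w) - 2 * a0^2,
                       interval = c(1e-3, 10 * order))$root
  poles / w3
}

# Bilinear transform of one analog section (conjugate pole pair or real
# pole), unit DC gain. Returns list(b, a) digital coefficients.
bilinear_section <- function(p, fs) {
  K <- 2 * fs
  if (abs(Im(p)) > 1e-9) {
    w02 <- Mod(p)^2
    tw <- -2 * Re(p)
    a0 <- K^2 + tw * K + w02
    b <- w02 * c(1, 2, 1) / a0
    a <- c(1, 2 * (w02 - K^2) / a0, (K^2 - tw * K + w02) / a0)
  } else {
    pr <- Re(p)
    a0 <- K - pr
    b <- -pr * c(1, 1) / a0
    a <- c(1, (-K - pr) / a0)
  }
  list(b = b, a = a)
}

# Apply an order-n Bessel low-pass (corner fc, sampling fs) to x.
bessel_lowpass <- function(x, fc, fs, order = 4) {
  if (fc >= fs / 2) stop("corner frequency must be below Nyquist (fs/2)", call. = FALSE)
  wa <- 2 * fs * tan(pi * fc / fs)   # pre-warped analog corner
  poles <- bessel_poles(order) * wa
  used <- rep(FALSE, length(poles))
  y <- x
  for (i in seq_along(poles)) {
    if (used[i]) next
    p <- poles[i]
    if (abs(Im(p)) > 1e-9 * Mod(p)) {
      j <- which(!used & abs(poles - Conj(p)) < 1e-6 * Mod(p))
      used[j[1]] <- TRUE
    }
    used[i] <- TRUE
    if (Im(p) < 0) p <- Conj(p)
    sec <- bilinear_section(p, fs)
    y <- as.numeric(signal::filter(sec$b, sec$a, y))
  }
  y
}

#' Low-pass filter a current trace
#'
#' Applies a Bessel-type low-pass filter (unit DC gain) realized digitally
#' by bilinear transform of the analog prototype with frequency pre-warping.
#' Bessel filters are the convention for single-channel records because
#' their near-linear phase preserves event edges without ringing.
#'
#' @param trace a [current_trace()]
#' @param fc corner (-3 dB) frequency, Hz; must be below Nyquist
#' @param order filter order (2, 4, or 8; default 8, the analysis-filter
#'   order for single-channel records)
#' @return a filtered [current_trace()]
#' @export
filter_trace <- function(trace, fc, order = 8) {
  stopifnot(is_current_trace(trace))
  if (!order %in% c(2, 4, 8)) stop("order must be 2, 4, or 8", call. = FALSE)
  out <- trace
  out$current <- bessel_lowpass(trace$current, fc, trace$sampling_rate, order)
  attr(out, "filter") <- list(fc = fc, order = order)
  out
}

#' Dead-time censoring of an event table
#'
#' Open events briefer than the dead time are unresolvable at the recording
#' bandwidth: they are removed and merged into the flanking closed time.
#' Censoring never creates open time. The same rule must be applied to
#' generator ground truth before comparing with an idealization.
#'
#' @param events data.frame with columns t_start, duration, state
#'   ("open"/"closed")
#' @param dead_time minimum resolvable open duration, s (default 446 us,
#'   2.5 x the rise time of the 2 kHz analysis filter)
#' @return censored, re-merged event data.frame
#' @export
censor_events <- function(events, dead_time = 446e-6) {
  ev <- as.data.frame(events)
  short_open <- ev$state == "open" & ev$duration < dead_time
  ev$state[short_open] <- "closed"
  if (nrow(ev) <= 1L) return(ev)
  # merge adjacent same-state runs
  grp <- cumsum(c(TRUE, ev$state[-1L] != ev$state[-nrow(ev)]))
  out <- do.call(rbind, lapply(split(ev, grp), function(g) {
    data.frame(t_start = g$t_start[1], duration = sum(g$duration),
               state = g$state[1], stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Idealize a single-channel record by half-amplitude threshold crossing
#'
#' Transitions are detected where the current crosses the midpoint between
#' the baseline and the open level; open events briefer than the dead time
#' are censored into the flanking closed time. When baseline / open level
#' are not supplied they are estimated from the two-mode structure of the
#' all-points amplitude distribution (2-means).
#'
#' @param trace a [current_trace()] (filter first with [filter_trace()] for
#'   noisy records)
#' @param baseline closed-channel current level, pA
#' @param open_level open-channel current level, pA (must differ from
#'   baseline)
#' @param dead_time minimum resolvable open duration, s (default 446 us)
#' @return object of class `event_list`: the event data.frame (t_start,
#'   duration, state, mean_amp) with attributes dead_time, baseline,
#'   open_level, total_time, sampling_rate
#' @export
idealize_half_threshold <- function(trace, baseline = NULL, open_level = NULL,
                                    dead_time = 446e-6) {
  stopifnot(is_current_trace(trace))
  x <- trace$current
  fs <- trace$sampling_rate
  if (!is.null(baseline) && !is.null(open_level) && open_level == baseline) {
    stop("open_level must differ from baseline", call. = FALSE)
  }
  if (is.null(baseline) || is.null(open_level)) {
    if (diff(range(x)) < 1e-9) {
      baseline <- stats::median(x)
      open_level <- NULL
    } else {
      km <- stats::kmeans(x, centers = stats::quantile(x, c(0.05, 0.95)))
      within_sd <- sqrt(km$tot.withinss / length(x))
      sep <- abs(diff(as.numeric(km$centers)))
      if (sep < 4 * max(within_sd, 1e-12)) {
        # unimodal amplitude distribution: no resolvable open level
        baseline <- stats::median(x)
        open_level <- NULL
      } else {
        big <- which.max(km$size)
        if (is.null(baseline)) baseline <- km$centers[big]
        if (is.null(open_level)) open_level <- km$centers[-big][1]
      }
    }
  }
  if (is.null(open_level)) {
    ev <- data.frame(t_start = 0, duration = length(x) / fs,
                     state = "closed", mean_amp = mean(x),
                     stringsAsFactors = FALSE)
    return(structure(ev, class = c("event_list", "data.frame"),
                     dead_time = dead_time, baseline = baseline,
                     open_level = NA_real_, total_time = length(x) / fs,
                     sampling_rate = fs))
  }
  frac <- (x - baseline) / (open_level - baseline)
  open <- frac > 0.5
  r <- rle(open)
  ends <- cumsum(r$lengths)
  starts <- c(1L, utils::head(ends, -1L) + 1L)
  ev <- data.frame(t_start = (starts - 1L) / fs,
                   duration = r$lengths / fs,
                   state = ifelse(r$values, "open", "closed"),
                   stringsAsFactors = FALSE)
  ev <- censor_events(ev, dead_time)
  ev$mean_amp <- vapply(seq_len(nrow(ev)), function(k) {
    i0 <- round(ev$t_start[k] * fs) + 1L
    i1 <- min(length(x), i0 + round(ev$duration[k] * fs) - 1L)
    mean(x[i0:i1])
  }, numeric(1))
  structure(ev, class = c("event_list", "data.frame"),
            dead_time = dead_time, baseline = baseline,
            open_level = open_level, total_time = length(x) / fs,
            sampling_rate = fs)
}

#' @export
print.event_list <- function(x, ...) {
  n_open <- sum(x$state == "open")
  cat(sprintf("<event_list>  %d events (%d open) over %.3g s, dead time %g us\n",
              nrow(x), n_open, attr(x, "total_time"),
              attr(x, "dead_time") * 1e6))
  NextMethod()
}

#' Single-Gaussian fit of the open-channel amplitude distribution
#'
#' Pools the current samples inside open events (trimming half a dead time
#' from each edge to exclude filter-rounded transitions) and fits a single
#' Gaussian component by maximum likelihood. The mean is reported signed
#' (inward openings negative).
#'
#' @param trace the [current_trace()] the events were idealized from
#' @param events an `event_list` from [idealize_half_threshold()]
#' @return object of class `amplitude_fit`: mean_amp (pA), sd (pA; 0 with a
#'   `degenerate` flag for noiseless records), n_points
#' @export
fit_amplitude_histogram <- function(trace, events) {
  stopifnot(is_current_trace(trace), inherits(events, "event_list"))
  op <- events[events$state == "open", , drop = FALSE]
  if (nrow(op) == 0L) stop("no open events survive dead-time censoring", call. = FALSE)
  fs <- trace$sampling_rate
  trim <- ceiling(attr(events, "dead_time") * fs / 2)
  samples <- unlist(lapply(seq_len(nrow(op)), function(k) {
    i0 <- round(op$t_start[k] * fs) + 1L
    i1 <- min(length(trace$current), i0 + round(op$duration[k] * fs) - 1L)
    if (i1 - i0 + 1L > 2L * trim + 3L) {
      i0 <- i0 + trim; i1 <- i1 - trim
    }
    trace$current[i0:i1]
  }))
  s <- stats::sd(samples)
  degenerate <- !is.finite(s) || s < 1e-12
  structure(list(mean_amp = mean(samples),
                 sd = if (degenerate) 0 else s,
                 n_points = length(samples),
                 degenerate = degenerate),
            class = "amplitude_fit")
}

#' @export
print.amplitude_fit <- function(x, ...) {
  cat(sprintf("<amplitude_fit>  mean = %.3g pA, sd = %.3g pA (n = %d)%s\n",
              x$mean_amp, x$sd, x$n_points,
              if (isTRUE(x$degenerate)) "  [degenerate: noiseless]" else ""))
  invisible(x)
}

#' Time-averaged open probability from an idealized record
#'
#' `100 * total open time / (total time x n_channels)`, percent.
#'
#' @param events an `event_list`
#' @param n_channels number of channels in the patch (>= 1)
#' @return open probability, percent
#' @export
single_channel_po <- function(events, n_channels = 1) {
  stopifnot(inherits(events, "event_list"))
  if (n_channels < 1) stop("n_channels must be >= 1", call. = FALSE)
  total <- attr(events, "total_time")
  if (total <= 0) stop("total_time must be > 0", call. = FALSE)
  100 * sum(events$duration[events$state == "open"]) / (total * n_channels)
}
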