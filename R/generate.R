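# Synthetic-data generators. Every generator is a pure function of its
# arguments (including the seed) and attaches its ground truth to the trace,
# so estimator tests are closed loops.

#' Generate a macroscopic whole-cell current trace
#'
#' Simulates the D-R-O-B scheme for the given protocol and converts the open
#' occupancy to current with `current(t) = -scale * p_O(t) / max(p_O) + noise`
#' (inward currents negative; `scale` is the peak current in pA).
#'
#' @param rates a [rate_set()]
#' @param protocol an [application_protocol()]
#' @param scale peak-current scale, pA (> 0)
#' @param sampling_rate sampling rate, Hz (default 10 kHz, the whole-cell
#'   acquisition rate)
#' @param noise a [noise_spec()]
#' @param construct optional construct label, e.g. "hGluN2B(L825V)"
#' @return a [current_trace()] with ground truth attached
#' @export
generate_whole_cell_trace <- function(rates, protocol, scale = 500,
                                      sampling_rate = 1e4,
                                      noise = noise_spec(),
                                      construct = NA_character_) {
  stopifnot(is_rate_set(rates), is_protocol(protocol))
  if (scale <= 0) stop("scale must be > 0", call. = FALSE)
  if (sampling_rate <= 0) stop("sampling_rate must be > 0", call. = FALSE)
  t_end <- max(protocol$epochs$t_end)
  t <- seq(0, t_end, by = 1 / sampling_rate)
  occ <- simulate_occupancies(rates, protocol, t)
  po_max <- max(occ$p_O)
  i_clean <- if (po_max > 0) -scale * occ$p_O / po_max else rep(0, length(t))
  i_noisy <- with_seed(noise$seed, i_clean + stats::rnorm(length(t), 0, noise$sd))
  tr <- current_trace(t, i_noisy, protocol = protocol, construct = construct)
  attr(tr, "ground_truth") <- list(kind = "whole_cell", rates = rates,
                                   scale = scale, po_max = po_max,
                                   noise_sd = noise$sd, seed = noise$seed)
  tr
}

#' Generate a synaptic-like response to a brief agonist pulse
#'
#' Emulates a response to a brief (~5 ms) application of saturating glutamate:
#' a rising phase shaped by a first-order exchange filter, followed by a decay
#' that is a sum of exponentials with the given amplitude weights.
#'
#' @param amp peak amplitude, pA (> 0; applied as an inward, negative current)
#' @param tau_components data.frame with columns `A` (relative amplitudes,
#'   > 0) and `tau` (decay time constants, s, > 0)
#' @param pulse_ms agonist pulse duration, ms (default 5)
#' @param sampling_rate Hz
#' @param rise_tau rise (exchange-filter) time constant, s; default 1 ms,
#'   representative of fast theta-tube exchange around a whole cell
#' @param noise a [noise_spec()]
#' @param duration total record length, s; default covers 6 x slowest tau
#' @return a [current_trace()] with ground truth attached
#' @export
#' @examples
#' tr <- generate_synaptic_trace(100, data.frame(A = 1, tau = 0.307))
generate_synaptic_trace <- function(amp, tau_components, pulse_ms = 5,
                                    sampling_rate = 1e4, rise_tau = 1e-3,
                                    noise = noise_spec(), duration = NULL) {
  if (!is.numeric(amp) || length(amp) != 1L || amp <= 0) {
    stop("amp must be a single value > 0 (pA)", call. = FALSE)
  }
  tc <- as.data.frame(tau_components)
  if (!all(c("A", "tau") %in% names(tc)) || any(tc$A <= 0) || any(tc$tau <= 0)) {
    stop("tau_components must have columns A > 0 and tau > 0", call. = FALSE)
  }
  if (nrow(tc) > 2L) stop("at most two decay components are supported", call. = FALSE)
  t_pulse <- pulse_ms / 1000
  if (is.null(duration)) duration <- t_pulse + 6 * max(tc$tau)
  t <- seq(0, duration, by = 1 / sampling_rate)
  w <- tc$A / sum(tc$A)
  shape <- numeric(length(t))
  rising <- t <= t_pulse
  if (rise_tau > 0) {
    shape[rising] <- (1 - exp(-t[rising] / rise_tau)) /
      (1 - exp(-t_pulse / rise_tau))
  } else {
    shape[rising] <- 1
  }
  td <- t[!rising] - t_pulse
  shape[!rising] <- colSums(w * exp(-outer(1 / tc$tau, td)))
  i_clean <- -amp * shape
  i_noisy <- with_seed(noise$seed, i_clean + stats::rnorm(length(t), 0, noise$sd))
  prot <- application_protocol(protocol_epoch(0, t_pulse, glutamate = 1000,
                                              glycine = 30),
                               exchange_tau = rise_tau)
  tr <- current_trace(t, i_noisy, protocol = prot)
  attr(tr, "ground_truth") <- list(kind = "synaptic", amp = amp,
                                   components = tc, pulse_s = t_pulse,
                                   rise_tau = rise_tau, noise_sd = noise$sd,
                                   seed = noise$seed)
  tr
}

#' Generate a stochastic single-channel record
#'
#' One channel alternating between closed and open states with exponentially
#' distributed dwell times, sampled as a square wave, optionally low-pass
#' filtered with a Bessel-type filter and corrupted with Gaussian noise.
#' The sample-quantized noise-free square wave defines the stored ground-truth
#' events (attribute `truth_events`); the continuous-time dwell sequence is
#' kept in `truth_dwells`.
#'
#' @param amp open-channel current, pA (inward openings are negative)
#' @param mean_open,mean_closed mean dwell times, s (> 0)
#' @param duration record length, s
#' @param sampling_rate Hz (default 25 kHz, the single-channel acquisition rate)
#' @param filter_fc Bessel corner frequency, Hz, or NULL for no filtering
#' @param noise a [noise_spec()]
#' @return a [current_trace()]; attribute `truth_events` holds the
#'   sample-quantized event table (t_start_s, duration_s, state), attribute
#'   `short_record` flags records shorter than 10 mean dwell cycles
#' @export
generate_single_channel_trace <- function(amp = -4.5, mean_open = 5e-3,
                                          mean_closed = 45e-3, duration = 10,
                                          sampling_rate = 2.5e4,
                                          filter_fc = NULL,
                                          noise = noise_spec()) {
  if (mean_open <= 0 || mean_closed <= 0) {
    stop("mean dwell times must be > 0", call. = FALSE)
  }
  if (amp == 0) stop("amp must be non-zero", call. = FALSE)
  dwells <- with_seed(noise$seed, {
    t_cum <- 0
    starts <- numeric(0); durs <- numeric(0); states <- character(0)
    open <- FALSE  # start closed
    while (t_cum < duration) {
      d <- stats::rexp(1, rate = 1 / if (open) mean_open else mean_closed)
      starts <- c(starts, t_cum)
      durs <- c(durs, d)
      states <- c(states, if (open) "open" else "closed")
      t_cum <- t_cum + d
      open <- !open
    }
    durs[length(durs)] <- duration - starts[length(durs)]
    data.frame(t_start = starts, duration = durs, state = states,
               stringsAsFactors = FALSE)
  })
  t <- seq(0, duration - 1 / sampling_rate, by = 1 / sampling_rate)
  # state at each sample time
  idx <- findInterval(t, dwells$t_start)
  open_at <- dwells$state[idx] == "open"
  i_clean <- ifelse(open_at, amp, 0)
  # sample-quantized truth events
  r <- rle(open_at)
  ends <- cumsum(r$lengths)
  starts_i <- c(1L, utils::head(ends, -1L) + 1L)
  truth_events <- data.frame(
    t_start = (starts_i - 1L) / sampling_rate,
    duration = r$lengths / sampling_rate,
    state = ifelse(r$values, "open", "closed"),
    stringsAsFactors = FALSE)
  i_out <- i_clean
  if (!is.null(filter_fc)) {
    i_out <- bessel_lowpass(i_out, filter_fc, sampling_rate)
  }
  i_out <- with_seed(if (is.null(noise$seed)) NULL else noise$seed + 1L,
                     i_out + stats::rnorm(length(t), 0, noise$sd))
  tr <- current_trace(t, i_out)
  attr(tr, "ground_truth") <- list(kind = "single_channel", amp = amp,
                                   mean_open = mean_open,
                                   mean_closed = mean_closed,
                                   filter_fc = filter_fc,
                                   noise_sd = noise$sd, seed = noise$seed)
  attr(tr, "truth_events") <- truth_events
  attr(tr, "truth_dwells") <- dwells
  attr(tr, "short_record") <- duration < 10 * (mean_open + mean_closed)
  tr
}

#' Generate paired I-V tables with and without Mg2+
#'
#' Without Mg2+ the current is linear in (V - V_rev); with Mg2+ it follows the
#' Woodhull-type Boltzmann relation (voltage-dependent block). Multiplicative
#' Gaussian noise of relative magnitude `noise_rel` is applied independently
#' to the two tables.
#'
#' @param fit_truth a [woodhull_fit()] holding the generating parameters
#' @param voltages membrane potentials, mV (should span both sides of V_rev)
#' @param mg Mg2+ concentration for the blocked table, mM
#' @param noise_rel relative noise fraction (0 for noiseless)
#' @param seed integer seed
#' @return list with data.frames `no_mg` and `mg` (columns v_mV, i), the Mg2+
#'   concentration, and the generating truth
#' @export
generate_iv_dataset <- function(fit_truth, voltages, mg = 1, noise_rel = 0,
                                seed = NULL) {
  stopifnot(inherits(fit_truth, "woodhull_fit"))
  if (length(voltages) < 4L) stop("need at least 4 voltages", call. = FALSE)
  i_lin <- fit_truth$g0 * (voltages - fit_truth$V_rev)
  i_blk <- woodhull_current(voltages, mg, fit_truth)
  with_seed(seed, {
    i_lin_n <- i_lin * (1 + stats::rnorm(length(i_lin), 0, noise_rel))
    i_blk_n <- i_blk * (1 + stats::rnorm(length(i_blk), 0, noise_rel))
    list(no_mg = data.frame(v_mV = voltages, i = i_lin_n),
         mg = data.frame(v_mV = voltages, i = i_blk_n),
         mg_mM = mg, truth = fit_truth)
  })
}

#' Generate a dose-response sample from a Hill-equation truth
#'
#' @param truth a [hill_fit()] or a list with EC50, h, I_max, mode
#' @param concs agonist/steroid concentrations, uM (> 0)
#' @param noise_rel multiplicative noise fraction
#' @param seed integer seed
#' @return data.frame (conc, response) with the truth attached as an attribute
#' @export
generate_dose_response <- function(truth, concs, noise_rel = 0, seed = NULL) {
  if (any(concs <= 0)) stop("concentrations must be > 0", call. = FALSE)
  resp <- hill_response(concs, truth)
  resp <- with_seed(seed, resp * (1 + stats::rnorm(length(resp), 0, noise_rel)))
  out <- data.frame(conc = concs, response = resp)
  attr(out, "ground_truth") <- truth
  out
}
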