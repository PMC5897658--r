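# Step 1 of the open-probability procedure: peak / steady-state / tau_d
# measurement and conversion to desensitization rate constants.

#' Convert desensitization extent and time constant to rate constants
#'
#' `k_d = D / tau_d` and `k_r = (1 - D) / tau_d`, so `k_d + k_r = 1/tau_d`
#' holds exactly.
#'
#' @param D desensitization fraction, `0 <= D < 1`
#' @param tau_d desensitization-onset time constant, s (> 0)
#' @return named vector `c(k_d, k_r)` in 1/s
#' @export
#' @examples
#' desens_rates(0.198, 1.1628)  # ~ (0.17, 0.69)
desens_rates <- function(D, tau_d) {
  if (!is.numeric(tau_d) || length(tau_d) != 1L || tau_d <= 0) {
    stop("tau_d must be a single value > 0", call. = FALSE)
  }
  if (!is.numeric(D) || length(D) != 1L || D < 0 || D >= 1) {
    stop("D must be a single value in [0, 1)", call. = FALSE)
  }
  c(k_d = D / tau_d, k_r = (1 - D) / tau_d)
}

#' Measure desensitization of a sustained-agonist response
#'
#' Locates the peak current within the early part of the glutamate epoch
#' (median-filtered over 1 ms to suppress single-sample spikes), averages the
#' steady-state current over the final part of the epoch, fits the onset of
#' desensitization with a single decaying exponential (offset fixed at
#' `I_SS`), and converts the results to rate constants:
#' `D = 1 - I_SS/I_P`, `k_d = D/tau_d`, `k_r = (1 - D)/tau_d`.
#'
#' Traces that desensitize by 2% or less are reported with `tau_d = NA`,
#' `k_d = 0` and `k_r = NA`: the onset rate analysis is not meaningful for
#' effectively non-desensitizing responses.
#'
#' @param trace a [current_trace()]; inward (negative) responses. If a
#'   protocol is attached, the first glutamate epoch without MK-801 is
#'   analyzed, otherwise the whole trace.
#' @param peak_window window from epoch onset searched for the peak, s
#' @param ss_fraction final fraction of the epoch averaged for `I_SS`
#'   (at least `ss_min` seconds)
#' @param ss_min minimum steady-state window, s
#' @param noise_floor minimum |peak| current, pA; smaller responses raise a
#'   "no response" error (non-responder criterion)
#' @return object of class `desens_fit` with fields I_P, I_SS, tau_d, D,
#'   k_d, k_r, fit_rmse, and flags `clipped` / `non_desensitizing`
#' @export
analyze_desensitization <- function(trace, peak_window = 0.5,
                                    ss_fraction = 0.1, ss_min = 0.2,
                                    noise_floor = 5) {
  stopifnot(is_current_trace(trace))
  t <- trace$time
  i <- trace$current
  if (!is.null(trace$protocol)) {
    ep <- trace$protocol$epochs
    sel <- which(ep$glutamate > 0 & ep$mk801 == 0)
    if (length(sel) == 0L) stop("protocol contains no glutamate-only epoch", call. = FALSE)
    a <- ep$t_start[sel[1]]; b <- ep$t_end[sel[1]]
    keep <- t >= a & t <= b
    t <- t[keep]; i <- i[keep]
  }
  if (length(t) < 10L) stop("glutamate epoch too short to analyze", call. = FALSE)
  fs <- trace$sampling_rate
  k_med <- max(3L, 2L * floor(fs * 1e-3 / 2) + 1L)  # ~1 ms, odd
  i_s <- stats::runmed(i, k_med, endrule = "median")

  pk_idx <- which(t <= t[1] + peak_window)
  ip_at <- pk_idx[which.min(i_s[pk_idx])]            # inward = most negative
  I_P <- i_s[ip_at]
  if (abs(I_P) < noise_floor) {
    stop(sprintf("no response: |peak| = %.2f pA below noise floor (%g pA)",
                 abs(I_P), noise_floor), call. = FALSE)
  }
  epoch_dur <- t[length(t)] - t[1]
  ss_len <- max(ss_fraction * epoch_dur, ss_min)
  ss_idx <- which(t >= t[length(t)] - ss_len)
  I_SS <- mean(i[ss_idx])

  clipped <- FALSE
  D <- 1 - I_SS / I_P
  if (D < 0) {
    warning("I_SS exceeds I_P; desensitization clipped at 0")
    D <- 0
    clipped <- TRUE
  }

  if (D <= 0.02) {
    fit <- list(I_P = I_P, I_SS = I_SS, tau_d = NA_real_, D = D,
                k_d = 0, k_r = NA_real_, fit_rmse = NA_real_,
                clipped = clipped, non_desensitizing = TRUE)
    return(structure(fit, class = "desens_fit"))
  }

  dec_idx <- seq(ip_at, length(t))
  td <- t[dec_idx] - t[ip_at]
  id <- i[dec_idx]
  amp0 <- I_P - I_SS
  # log-linear starting value for tau
  pos <- (id - I_SS) / amp0
  ok <- pos > 0.05
  tau0 <- if (sum(ok) > 2) {
    cf <- unname(stats::coef(stats::lm(log(pos[ok]) ~ td[ok])))
    if (is.finite(cf[2]) && cf[2] < 0) -1 / cf[2] else epoch_dur / 3
  } else epoch_dur / 3
  df <- data.frame(td = td, id = id)
  fit_nls <- minpack.lm::nlsLM(
    id ~ I_SS + A * exp(-td / tau),
    data = df, start = list(A = amp0, tau = tau0),
    lower = c(A = -Inf, tau = 1e-6),
    control = minpack.lm::nls.lm.control(maxiter = 200))
  tau_d <- stats::coef(fit_nls)[["tau"]]
  rates <- desens_rates(D, tau_d)
  fit <- list(I_P = I_P, I_SS = I_SS, tau_d = tau_d, D = D,
              k_d = rates[["k_d"]], k_r = rates[["k_r"]],
              fit_rmse = sqrt(mean(stats::residuals(fit_nls)^2)),
              clipped = clipped, non_desensitizing = FALSE)
  structure(fit, class = "desens_fit")
}

#' @export
print.desens_fit <- function(x, ...) {
  cat("<desens_fit>\n")
  cat(sprintf("  I_P = %.2f pA   I_SS = %.2f pA   D = %.3f\n", x$I_P, x$I_SS, x$D))
  if (isTRUE(x$non_desensitizing)) {
    cat("  effectively non-desensitizing (D <= 2%): rate analysis skipped\n")
  } else {
    cat(sprintf("  tau_d = %.4g s   k_d = %.4g /s   k_r = %.4g /s   rmse = %.3g pA\n",
                x$tau_d, x$k_d, x$k_r, x$fit_rmse))
  }
  invisible(x)
}
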