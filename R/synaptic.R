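# Analysis of synaptic-like responses to brief agonist pulses: deactivation
# fits, steroid potentiation, deceleration, and the charge-transfer factor.

#' Fit the deactivation of a synaptic-like response
#'
#' Fits the post-pulse decay with one or two exponential components from the
#' post-pulse extremum to the end of the record. In `auto` mode the second
#' component is kept only when it reduces the residual sum of squares
#' significantly (extra-sum-of-squares F-test at 0.05). The reported time
#' constant `tau_report` is tau for a single component and the
#' amplitude-weighted `tau_w = (A1 tau1 + A2 tau2)/(A1 + A2)` for two.
#'
#' @param trace a [current_trace()] from a brief-pulse protocol (pulse
#'   <= 10 ms followed by several decay time constants of record)
#' @param n_components 1, 2, or "auto"
#' @return object of class `deactivation_fit`: n_components, A1, A2, tau1,
#'   tau2 (tau1 <= tau2), tau_report (s), peak (fitted post-pulse peak, pA,
#'   signed), fit_rmse
#' @export
fit_deactivation <- function(trace, n_components = c("auto", "1", "2")) {
  stopifnot(is_current_trace(trace))
  n_components <- as.character(n_components[1])
  if (!n_components %in% c("auto", "1", "2")) {
    stop('n_components must be 1, 2, or "auto"', call. = FALSE)
  }
  t <- trace$time; i <- trace$current
  t_pulse <- if (!is.null(trace$protocol)) {
    ep <- trace$protocol$epochs
    sel <- which(ep$glutamate > 0)
    if (length(sel) == 0L) stop("protocol contains no agonist pulse", call. = FALSE)
    if (ep$t_end[sel[1]] - ep$t_start[sel[1]] > 0.010) {
      stop("agonist pulse longer than 10 ms: not a synaptic-like protocol",
           call. = FALSE)
    }
    ep$t_end[sel[1]]
  } else {
    t[which.min(i)]   # fall back to the raw extremum
  }
  post <- which(t >= t_pulse)
  pk <- post[which.min(i[post])]
  dec <- seq(pk, length(t))
  td <- t[dec] - t[pk]
  id <- i[dec]
  if (abs(mean(utils::tail(id, max(5L, length(id) %/% 20)))) >
      0.8 * abs(id[1])) {
    stop("response does not decay after the pulse", call. = FALSE)
  }

  peak_amp <- id[1]          # signed, inward negative
  # single-exponential fit
  tau0 <- {
    pos <- id / peak_amp
    ok <- pos > 0.05
    if (sum(ok) > 2) {
      cf <- unname(stats::coef(stats::lm(log(pos[ok]) ~ td[ok])))
      if (is.finite(cf[2]) && cf[2] < 0) -1 / cf[2] else max(td) / 3
    } else max(td) / 3
  }
  df <- data.frame(td = td, id = id)
  f1 <- minpack.lm::nlsLM(id ~ A1 * exp(-td / tau1), data = df,
                          start = list(A1 = peak_amp, tau1 = tau0),
                          lower = c(A1 = -Inf, tau1 = 1e-6),
                          control = minpack.lm::nls.lm.control(maxiter = 500))
  rss1 <- sum(stats::residuals(f1)^2)

  f2 <- NULL
  if (n_components != "1") {
    f2 <- tryCatch(minpack.lm::nlsLM(
      id ~ A1 * exp(-td / tau1) + A2 * exp(-td / tau2), data = df,
      start = list(A1 = peak_amp * 0.6, tau1 = tau0 * 0.3,
                   A2 = peak_amp * 0.4, tau2 = tau0 * 2),
      lower = c(A1 = -Inf, tau1 = 1e-6, A2 = -Inf, tau2 = 1e-6),
      control = minpack.lm::nls.lm.control(maxiter = 500)),
      error = function(e) NULL)
  }

  use2 <- switch(n_components,
    "1" = FALSE,
    "2" = !is.null(f2),
    "auto" = {
      if (is.null(f2)) FALSE else {
        rss2 <- sum(stats::residuals(f2)^2)
        n <- length(td)
        # guard: near-perfect single fit leaves nothing for an F-test
        if (rss1 < 1e-12 * sum(id^2) || rss2 <= 0) FALSE else {
          fstat <- ((rss1 - rss2) / 2) / (rss2 / (n - 4))
          fstat > 0 && stats::pf(fstat, 2, n - 4, lower.tail = FALSE) < 0.05
        }
      }
    })

  if (use2) {
    cf <- stats::coef(f2)
    comps <- data.frame(A = c(cf[["A1"]], cf[["A2"]]),
                        tau = c(cf[["tau1"]], cf[["tau2"]]))
    comps <- comps[order(comps$tau), ]
    tau_w <- sum(comps$A * comps$tau) / sum(comps$A)
    res <- stats::residuals(f2)
    out <- list(n_components = 2L, A1 = comps$A[1], A2 = comps$A[2],
                tau1 = comps$tau[1], tau2 = comps$tau[2],
                tau_report = tau_w, peak = sum(comps$A),
                fit_rmse = sqrt(mean(res^2)))
  } else {
    cf <- stats::coef(f1)
    res <- stats::residuals(f1)
    out <- list(n_components = 1L, A1 = cf[["A1"]], A2 = NA_real_,
                tau1 = cf[["tau1"]], tau2 = NA_real_,
                tau_report = cf[["tau1"]], peak = cf[["A1"]],
                fit_rmse = sqrt(mean(res^2)))
  }
  if (max(td) < 3 * out$tau_report) {
    warning("decay recorded for less than 3 time constants; tau may be biased")
  }
  structure(out, class = "deactivation_fit")
}

#' @export
print.deactivation_fit <- function(x, ...) {
  cat(sprintf("<deactivation_fit>  %d component(s)\n", x$n_components))
  if (x$n_components == 1L) {
    cat(sprintf("  A = %.3g pA   tau = %.4g s   rmse = %.3g pA\n",
                x$A1, x$tau1, x$fit_rmse))
  } else {
    cat(sprintf("  A1 = %.3g pA tau1 = %.4g s | A2 = %.3g pA tau2 = %.4g s\n",
                x$A1, x$tau1, x$A2, x$tau2))
    cat(sprintf("  tau_w = %.4g s   rmse = %.3g pA\n", x$tau_report, x$fit_rmse))
  }
  invisible(x)
}

#' Steroid potentiation of the response amplitude
#'
#' `100 * (|peak_steroid| - |peak_control|) / |peak_control|`, percent.
#'
#' @param peak_steroid,peak_control response peaks, pA (same sign; fitted
#'   model peaks are recommended for noise robustness)
#' @return potentiation in percent
#' @export
#' @examples
#' potentiation_percent(-37, -20)  # 85
potentiation_percent <- function(peak_steroid, peak_control) {
  if (peak_control == 0) stop("control peak must be non-zero", call. = FALSE)
  if (sign(peak_steroid) != sign(peak_control) && peak_steroid != 0) {
    stop("peaks must have the same sign", call. = FALSE)
  }
  100 * (abs(peak_steroid) - abs(peak_control)) / abs(peak_control)
}

#' Deceleration of deactivation by a steroid
#'
#' Ratio of deactivation time constants, steroid / control.
#'
#' @param tau_steroid,tau_control reported time constants, s (> 0)
#' @return dimensionless ratio
#' @export
#' @examples
#' deceleration(0.499, 0.307)  # ~1.63
deceleration <- function(tau_steroid, tau_control) {
  if (tau_steroid <= 0 || tau_control <= 0) {
    stop("time constants must be > 0", call. = FALSE)
  }
  tau_steroid / tau_control
}

#' Charge-transfer enhancement factor
#'
#' The charge carried by a synaptic-like response is proportional to the
#' product of its amplitude and its decay time course, so the steroid-induced
#' enhancement factors combine multiplicatively:
#' `(1 + potentiation/100) * deceleration`.
#'
#' @param potentiation amplitude potentiation, percent
#' @param deceleration tau ratio from [deceleration()] (> 0)
#' @return fold-change in charge transfer
#' @export
#' @examples
#' charge_transfer_factor(98.7, 1.63)  # ~3.24
charge_transfer_factor <- function(potentiation, deceleration) {
  if (deceleration <= 0) stop("deceleration must be > 0", call. = FALSE)
  (1 + potentiation / 100) * deceleration
}

#' Summarize a control/steroid pair of synaptic-like responses
#'
#' Fits both deactivations, then computes the amplitude potentiation (from
#' the fitted peaks), the deceleration (ratio of reported time constants),
#' and the charge-transfer factor.
#'
#' @param control_trace,steroid_trace paired [current_trace()] records
#' @param n_components passed to [fit_deactivation()]
#' @return object of class `synaptic_summary` with the two `deactivation_fit`
#'   objects and fields potentiation (percent), deceleration,
#'   charge_transfer
#' @export
synaptic_summary <- function(control_trace, steroid_trace,
                             n_components = "auto") {
  fc <- fit_deactivation(control_trace, n_components)
  fs <- fit_deactivation(steroid_trace, n_components)
  pot <- potentiation_percent(fs$peak, fc$peak)
  dec <- deceleration(fs$tau_report, fc$tau_report)
  structure(list(control = fc, steroid = fs, potentiation = pot,
                 deceleration = dec,
                 charge_transfer = charge_transfer_factor(pot, dec)),
            class = "synaptic_summary")
}

#' @export
print.synaptic_summary <- function(x, ...) {
  cat("<synaptic_summary>\n")
  cat(sprintf("  potentiation = %.1f %%   deceleration = %.3g   charge transfer = %.3g-fold\n",
              x$potentiation, x$deceleration, x$charge_transfer))
  cat(sprintf("  tau control = %.4g s   tau steroid = %.4g s\n",
              x$control$tau_report, x$steroid$tau_report))
  invisible(x)
}
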