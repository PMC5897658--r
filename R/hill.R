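# Hill-equation fitting: agonist concentration-response (normalized logistic)
# and steroid potentiation (free maximum).

#' Hill-equation parameter set
#'
#' In agonist mode the normalized response is
#' `I = 1 / (1 + (EC50/[agonist])^h)` (I_max fixed at 1); in potentiation
#' mode `I = I_max / (1 + (EC50/[steroid])^h)` with the potentiation
#' asymptote `I_max` (percent) free.
#'
#' @param EC50 half-maximal concentration, uM (> 0)
#' @param h Hill coefficient (> 0)
#' @param I_max maximal response (1 in agonist mode; percent potentiation in
#'   potentiation mode)
#' @param mode "agonist" or "potentiation"
#' @param se_EC50,se_h standard errors (NA when constructed by hand)
#' @return object of class `hill_fit`
#' @export
hill_fit <- function(EC50, h, I_max = 1, mode = c("agonist", "potentiation"),
                     se_EC50 = NA_real_, se_h = NA_real_) {
  mode <- match.arg(mode)
  if (EC50 <= 0) stop("EC50 must be > 0", call. = FALSE)
  if (h <= 0) stop("Hill coefficient must be > 0", call. = FALSE)
  structure(list(EC50 = EC50, h = h, I_max = I_max, mode = mode,
                 se_EC50 = se_EC50, se_h = se_h, logEC50 = log10(EC50)),
            class = "hill_fit")
}

#' @export
print.hill_fit <- function(x, ...) {
  cat(sprintf("<hill_fit> (%s)\n", x$mode))
  cat(sprintf("  EC50 = %.4g uM (se %.3g)   h = %.3g (se %.3g)   I_max = %.4g\n",
              x$EC50, x$se_EC50, x$h, x$se_h, x$I_max))
  invisible(x)
}

#' Evaluate the Hill equation
#'
#' @param conc concentrations, uM (> 0)
#' @param fit a [hill_fit()]
#' @return predicted responses
#' @export
#' @examples
#' hill_response(30, hill_fit(9.5, 1.5, I_max = 570, mode = "potentiation"))
hill_response <- function(conc, fit) {
  stopifnot(inherits(fit, "hill_fit"))
  if (any(conc <= 0)) stop("conc must be > 0", call. = FALSE)
  fit$I_max / (1 + (fit$EC50 / conc)^fit$h)
}

#' Fit the Hill equation to dose-response data
#'
#' Nonlinear least squares on a log-EC50 internal parameterization (for
#' conditioning; group comparisons in this field are conventionally performed
#' on logEC50 and log h, which the returned object exposes). In agonist mode
#' `I_max` is fixed at 1 and responses are expected normalized to the
#' saturating response; `normalize = "max-dose"` divides by the response at
#' the highest dose first.
#'
#' @param doses concentrations, uM (> 0, at least 4 distinct values)
#' @param responses measured responses (same length)
#' @param mode "agonist" or "potentiation"
#' @param normalize "none" or "max-dose" (agonist mode only)
#' @return a [hill_fit()] with standard errors from the fit covariance
#' @export
fit_hill <- function(doses, responses, mode = c("agonist", "potentiation"),
                     normalize = c("none", "max-dose")) {
  mode <- match.arg(mode)
  normalize <- match.arg(normalize)
  if (length(doses) != length(responses)) {
    stop("doses and responses must have the same length", call. = FALSE)
  }
  if (any(doses <= 0)) stop("doses must be > 0", call. = FALSE)
  if (length(unique(doses)) < 4L) {
    stop("need at least 4 distinct dose points", call. = FALSE)
  }
  if (stats::sd(responses) < 1e-10 * max(abs(responses), 1e-12)) {
    stop("no dose dependence: all responses are equal", call. = FALSE)
  }
  if (mode == "agonist" && normalize == "max-dose") {
    responses <- responses / responses[which.max(doses)][1]
  }
  ord <- order(doses)
  r_ord <- responses[ord]
  if (max(-diff(r_ord), 0) > 0.15 * diff(range(responses))) {
    warning("responses are not monotone in dose beyond noise; check the data")
  }
  rmax0 <- max(responses)
  ec50_0 <- doses[ord][which.min(abs(responses[ord] - rmax0 / 2))]
  df <- data.frame(d = doses, r = responses)
  if (mode == "agonist") {
    fit <- minpack.lm::nlsLM(
      r ~ 1 / (1 + exp(h * (lec - log(d)))),
      data = df, start = list(lec = log(ec50_0), h = 1.2),
      lower = c(lec = log(1e-6), h = 1e-3),
      control = minpack.lm::nls.lm.control(maxiter = 500))
    imax <- 1
  } else {
    fit <- minpack.lm::nlsLM(
      r ~ imax / (1 + exp(h * (lec - log(d)))),
      data = df, start = list(lec = log(ec50_0), h = 1.2, imax = rmax0),
      lower = c(lec = log(1e-6), h = 1e-3, imax = 1e-9),
      control = minpack.lm::nls.lm.control(maxiter = 500))
    imax <- stats::coef(fit)[["imax"]]
  }
  cf <- stats::coef(fit)
  se <- tryCatch(sqrt(diag(stats::vcov(fit))), error = function(e) rep(NA_real_, length(cf)))
  names(se) <- names(cf)
  ec50 <- exp(cf[["lec"]])
  hill_fit(ec50, cf[["h"]], I_max = imax, mode = mode,
           se_EC50 = ec50 * se[["lec"]], se_h = se[["h"]])
}
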