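# Woodhull-type Boltzmann analysis of voltage-dependent Mg2+ block.
# The block site senses a fraction delta of the membrane field, so the
# apparent dissociation constant varies exponentially with voltage:
# K_d(V) = a * exp(b V) with a = K_d(0 mV) and b = 2 delta F / (R T).

FARADAY <- 96485      # C/mol
GAS_R <- 8.314        # J/(mol K)

#' Woodhull block parameter set
#'
#' @param g0 conductance of the unblocked linear I-V (normalized units or nS)
#' @param V_rev reversal potential, mV
#' @param a apparent K_d for Mg2+ at 0 mV, mM (> 0)
#' @param delta electrical distance of the block site from the outside,
#'   in `[0, 1]`
#' @param T_K absolute temperature, K (default 298.15, room temperature)
#' @return object of class `woodhull_fit`; field `b` holds
#'   `2 delta F / (R T)` in 1/V
#' @export
woodhull_fit <- function(g0, V_rev, a, delta, T_K = 298.15) {
  if (a <= 0) stop("a = K_d(0 mV) must be > 0", call. = FALSE)
  if (delta < 0 || delta > 1) stop("delta must be in [0, 1]", call. = FALSE)
  structure(list(g0 = g0, V_rev = V_rev, a = a, delta = delta, T = T_K,
                 b = 2 * delta * FARADAY / (GAS_R * T_K),
                 unreliable = FALSE,
                 se_a = NA_real_, se_delta = NA_real_),
            class = "woodhull_fit")
}

#' @export
print.woodhull_fit <- function(x, ...) {
  cat("<woodhull_fit>\n")
  cat(sprintf("  g0 = %.4g   V_rev = %.3g mV   K_d(0 mV) = %.4g mM   delta = %.3g\n",
              x$g0, x$V_rev, x$a, x$delta))
  cat(sprintf("  b = %.4g /V   T = %.5g K%s\n", x$b, x$T,
              if (isTRUE(x$unreliable)) "   [UNRELIABLE FIT]" else ""))
  invisible(x)
}

#' Current under voltage-dependent Mg2+ block
#'
#' `I(V) = a g0 (V - V_rev) / (a + [Mg2+] exp(-b V))`, with V in mV at the
#' interface and converted to volts inside the exponential.
#'
#' @param V membrane potentials, mV
#' @param mg Mg2+ concentration, mM
#' @param fit a [woodhull_fit()]
#' @return currents in the units of `g0 * mV`
#' @export
woodhull_current <- function(V, mg, fit) {
  stopifnot(inherits(fit, "woodhull_fit"))
  if (mg < 0) stop("mg must be >= 0", call. = FALSE)
  fit$a * fit$g0 * (V - fit$V_rev) / (fit$a + mg * exp(-fit$b * V / 1000))
}

#' Fit the Woodhull block model to paired I-V tables
#'
#' Stage 1: the Mg2+-free I-V is fit by a straight line, giving `g0` and
#' `V_rev`; both tables are normalized so that the unblocked slope is 1.
#' Stage 2: the normalized with-Mg2+ data are fit by nonlinear least squares
#' to the Boltzmann relation with `a = K_d(0 mV)` and `delta` free (`V_rev`
#' is carried over from stage 1, not refloated).
#'
#' When the with-Mg2+ data are essentially indistinguishable from the
#' unblocked line (maximum observed inhibition < 5%) the fit is flagged
#' `unreliable`: neither K_d(0 mV) nor delta is identified.
#'
#' @param iv_no_mg,iv_mg data.frames with columns `v_mV` and `i`
#' @param mg Mg2+ concentration of the blocked table, mM (> 0)
#' @param T_K absolute temperature, K
#' @return a [woodhull_fit()] (normalized: `g0 = 1`), with standard errors
#'   `se_a`, `se_delta` and the `unreliable` flag
#' @export
fit_woodhull <- function(iv_no_mg, iv_mg, mg, T_K = 298.15) {
  for (tab in list(iv_no_mg, iv_mg)) {
    if (!is.data.frame(tab) || !all(c("v_mV", "i") %in% names(tab))) {
      stop("I-V tables must have columns v_mV and i", call. = FALSE)
    }
  }
  if (!is.numeric(mg) || length(mg) != 1L || mg <= 0) {
    stop("mg must be a single value > 0 mM", call. = FALSE)
  }
  lin <- stats::lm(i ~ v_mV, data = iv_no_mg)
  g0 <- stats::coef(lin)[["v_mV"]]
  if (g0 <= 0) stop("unblocked I-V has non-positive slope", call. = FALSE)
  v_rev <- -stats::coef(lin)[["(Intercept)"]] / g0
  i_mg_n <- iv_mg$i / g0       # normalize: unblocked slope -> 1
  v <- iv_mg$v_mV

  # identifiability screen: how much block is there to fit?
  lin_pred <- v - v_rev
  away <- abs(lin_pred) > 0.05 * max(abs(lin_pred))
  inhib <- 1 - i_mg_n[away] / lin_pred[away]
  unreliable <- max(inhib, na.rm = TRUE) < 0.05

  bfac <- 2 * FARADAY / (GAS_R * T_K) / 1000   # per mV, times delta
  model <- function(la, delta) {
    exp(la) * (v - v_rev) / (exp(la) + mg * exp(-delta * bfac * v))
  }
  rss <- function(p) sum((i_mg_n - model(p[1], p[2]))^2)
  # multi-start over the physical delta range (the surface can be flat in
  # one parameter when block is weak or voltage-independent)
  lower <- c(log(1e-6), 0); upper <- c(log(1e6), 1)
  best <- NULL
  for (d0 in c(0.1, 0.45, 0.8)) {
    o <- stats::optim(c(log(mg), d0), rss, method = "L-BFGS-B",
                      lower = lower, upper = upper,
                      control = list(factr = 1e3))
    if (is.null(best) || o$value < best$value) best <- o
  }
  cf <- c(la = best$par[1], delta = best$par[2])
  # covariance from the finite-difference Jacobian at the optimum
  se <- tryCatch({
    n <- length(v)
    J <- vapply(1:2, function(j) {
      hstep <- 1e-5 * max(abs(cf[j]), 1e-3)
      pp <- cf; pp[j] <- pp[j] + hstep
      (model(pp[1], pp[2]) - model(cf[1], cf[2])) / hstep
    }, numeric(n))
    sigma2 <- best$value / max(n - 2, 1)
    sqrt(diag(sigma2 * solve(crossprod(J))))
  }, error = function(e) c(NA_real_, NA_real_))
  out <- woodhull_fit(1, v_rev, exp(cf[["la"]]), cf[["delta"]], T_K = T_K)
  out$se_a <- exp(cf[["la"]]) * se[1]
  out$se_delta <- se[2]
  out$unreliable <- unreliable
  if (unreliable) {
    warning("Mg2+ block smaller than 5%: K_d(0 mV) and delta are unreliable")
  }
  out
}

#' Fractional inhibition by Mg2+ at a given potential
#'
#' `1 - I_withMg / I_withoutMg` evaluated from the Boltzmann relation.
#'
#' @param V membrane potential, mV (must differ from V_rev, where the ratio
#'   is undefined)
#' @param mg Mg2+ concentration, mM
#' @param fit a [woodhull_fit()]
#' @return inhibition fraction in `[0, 1]`
#' @export
relative_inhibition <- function(V, mg, fit) {
  stopifnot(inherits(fit, "woodhull_fit"))
  if (mg < 0) stop("mg must be >= 0", call. = FALSE)
  if (any(abs(V - fit$V_rev) < 1e-9)) {
    stop("inhibition is an undefined 0/0 ratio at V = V_rev", call. = FALSE)
  }
  1 - fit$a / (fit$a + mg * exp(-fit$b * V / 1000))
}

#' Correct a holding potential for the liquid junction potential
#'
#' @param V_hold nominal holding potential, mV
#' @param junction junction potential, mV (default 14, the value for the
#'   gluconate-based intracellular solution used here)
#' @return corrected potential, mV
#' @export
#' @examples
#' correct_junction_potential(-60)  # -74
correct_junction_potential <- function(V_hold, junction = 14) {
  V_hold - junction
}
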