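# Linear master-equation machinery for the four-state D-R-O-B scheme.
# The scheme is linear, so each constant-concentration stretch is solved
# exactly with the matrix propagator; only the solution-exchange transient
# (time-dependent MK-801 concentration) is sub-stepped.

# Matrix exponential by scaling-and-squaring with a Taylor core.
# For the 4x4 generators used here this is accurate to ~1e-13.
expm_ss <- function(M) {
  nrm <- max(colSums(abs(M)))
  s <- if (nrm > 0.5) ceiling(log2(nrm / 0.5)) else 0L
  B <- M / 2^s
  E <- diag(nrow(M))
  term <- E
  for (k in 1:13) {
    term <- term %*% B / k
    E <- E + term
  }
  if (s > 0) for (i in seq_len(s)) E <- E %*% E
  E
}

# Occupancies at offsets `dts` (>= 0) from initial state p0 under constant
# generator A, via eigendecomposition: p(t) = V diag(exp(lambda t)) V^-1 p0.
# Falls back to stepwise squaring if the eigenbasis is ill-conditioned.
prop_const_grid <- function(A, p0, dts) {
  if (length(dts) == 0L) return(matrix(numeric(0), nrow = 4))
  eg <- try(eigen(A), silent = TRUE)
  ok <- !inherits(eg, "try-error")
  if (ok) {
    W <- try(solve(eg$vectors, p0), silent = TRUE)
    ok <- !inherits(W, "try-error") &&
      kappa(eg$vectors, exact = FALSE) < 1e10
  }
  if (ok) {
    E <- exp(outer(eg$values, dts))          # 4 x n, possibly complex
    out <- Re(eg$vectors %*% (E * W))
    return(out)
  }
  # fallback: march with the one-step propagator (dts assumed sorted)
  out <- matrix(NA_real_, 4, length(dts))
  p <- p0
  t_prev <- 0
  for (i in seq_along(dts)) {
    p <- expm_ss(A * (dts[i] - t_prev)) %*% p
    out[, i] <- p
    t_prev <- dts[i]
  }
  out
}

prop_const_state <- function(A, p0, dt) {
  if (dt <= 0) return(p0)
  drop(expm_ss(A * dt) %*% p0)
}

# Core integrator: march over contiguous segments (columns t_start, t_end,
# mk801), starting at state p0 / effective concentration c0 at time
# segments$t_start[1], recording occupancies at the grid times `t` that fall
# inside the segments. Within each segment the effective MK-801 concentration
# relaxes first-order from its entry value to the segment target with time
# constant exchange_tau; the relaxed remainder is solved in closed form.
sim_core <- function(rates, segments, exchange_tau, t, p0, c0 = 0) {
  n <- length(t)
  out <- matrix(NA_real_, 4, n)
  p_cur <- p0
  c_cur <- c0
  k <- 1L
  eps <- 1e-12
  for (i in seq_len(nrow(segments))) {
    a <- segments$t_start[i]
    b <- segments$t_end[i]
    target <- segments$mk801[i]
    t_cur <- a
    tol_abs <- 1e-9 * max(1, target, c_cur)
    if (exchange_tau <= 0 || abs(c_cur - target) <= tol_abs) {
      T_relax <- 0
      c_a <- target
    } else {
      T_relax <- min(b - a, exchange_tau * log(abs(c_cur - target) / tol_abs))
      c_a <- c_cur
    }
    t_relax_end <- a + T_relax
    c_fun <- function(tt) target + (c_a - target) * exp(-(tt - a) / exchange_tau)

    # transient phase: sub-step with midpoint concentration
    advance_to <- function(tt) {
      if (tt <= t_cur + eps) return(invisible(NULL))
      m <- max(1L, ceiling((tt - t_cur) / (exchange_tau / 20)))
      dt_sub <- (tt - t_cur) / m
      for (j in seq_len(m)) {
        t_mid <- t_cur + (j - 0.5) * dt_sub
        A <- scheme_generator(rates, c_fun(t_mid))
        p_cur <<- drop(expm_ss(A * dt_sub) %*% p_cur)
      }
      t_cur <<- tt
      invisible(NULL)
    }
    if (T_relax > 0) {
      k_tr <- findInterval(t_relax_end + eps, t)
      while (k <= min(n, k_tr)) {
        if (t[k] < a - eps) { k <- k + 1L; next }
        advance_to(t[k])
        out[, k] <- p_cur
        k <- k + 1L
      }
      advance_to(t_relax_end)
    }
    c_cur <- target

    # constant phase to segment end
    A <- scheme_generator(rates, target)
    k_end <- findInterval(b + eps, t)
    if (k_end >= k) {
      idx <- k:k_end
      idx <- idx[t[idx] >= t_cur - eps]
      if (length(idx)) out[, idx] <- prop_const_grid(A, p_cur, t[idx] - t_cur)
      k <- k_end + 1L
    }
    p_cur <- prop_const_state(A, p_cur, b - t_cur)
  }
  list(p = out, p_final = p_cur, c_final = c_cur)
}

#' Simulate state occupancies for an application protocol
#'
#' Solves the linear master equation of the D-R-O-B scheme on a uniform time
#' grid. All occupancy starts in the closed state R at glutamate onset (the
#' agonist binding steps are not modelled; at saturating glutamate receptors
#' are effectively all doubly liganded). Before glutamate onset occupancies
#' are held at p_R = 1 and the corresponding current is zero. The effective
#' MK-801 concentration follows the protocol's epoch targets through a
#' first-order solution-exchange filter (`exchange_tau`).
#'
#' Constant-concentration stretches are solved exactly with the matrix
#' propagator; the exchange transient is sub-stepped at `exchange_tau/20`.
#'
#' @param rates a [rate_set()]
#' @param protocol an [application_protocol()]
#' @param t_grid uniform, strictly increasing time grid, s
#' @return object of class `state_occupancy`: list with `t`, `p_D`, `p_R`,
#'   `p_O`, `p_B` (fractions summing to 1 at every point)
#' @export
#' @examples
#' rts <- rate_set(k_d = 0.17, k_r = 0.69, k_o = 27.8, k_c = 200)
#' prot <- application_protocol(protocol_epoch(0, 2, glutamate = 1000),
#'                              exchange_tau = 0)
#' occ <- simulate_occupancies(rts, prot, seq(0, 2, by = 1e-3))
simulate_occupancies <- function(rates, protocol, t_grid) {
  stopifnot(is_rate_set(rates), is_protocol(protocol))
  if (length(t_grid) < 2L) stop("t_grid must have at least two points", call. = FALSE)
  dt <- diff(t_grid)
  if (any(dt <= 0)) stop("t_grid must be strictly increasing", call. = FALSE)
  if (max(abs(dt - dt[1])) > 1e-9 * dt[1] + 1e-15) {
    stop("t_grid must be uniform", call. = FALSE)
  }
  n <- length(t_grid)
  p <- matrix(NA_real_, 4, n)
  t_on <- glutamate_onset(protocol)
  if (is.na(t_on)) {
    p[] <- c(0, 1, 0, 0)
  } else {
    pre <- t_grid < t_on - 1e-12
    p[, pre] <- c(0, 1, 0, 0)
    t_hi <- max(t_grid[n], max(protocol$epochs$t_end))
    segs <- protocol_segments(protocol, t_on, t_hi)
    res <- sim_core(rates, segs, protocol$exchange_tau,
                    t_grid[!pre], p0 = c(0, 1, 0, 0), c0 = 0)
    p[, !pre] <- res$p
  }
  structure(list(t = t_grid, p_D = p[1, ], p_R = p[2, ],
                 p_O = p[3, ], p_B = p[4, ]),
            class = "state_occupancy")
}

#' @export
print.state_occupancy <- function(x, ...) {
  cat(sprintf("<state_occupancy>  %d points, t in [%g, %g] s\n",
              length(x$t), min(x$t), max(x$t)))
  cat(sprintf("  final occupancies: D=%.4f R=%.4f O=%.4f B=%.4f\n",
              x$p_D[length(x$t)], x$p_R[length(x$t)],
              x$p_O[length(x$t)], x$p_B[length(x$t)]))
  invisible(x)
}

#' Stationary occupancies of the scheme
#'
#' For `mk801 = 0` the three-state sub-scheme D-R-O has the closed-form
#' stationary distribution with
#' `p_O = (k_o/k_c) / (1 + k_d/k_r + k_o/k_c)`. With MK-801 present and
#' `k_u > 0` the full four-state balance applies; with `k_u = 0` the blocked
#' state is absorbing and the only stationary distribution is `p_B = 1`
#' (flagged via the `"absorbing"` attribute).
#'
#' @param rates a [rate_set()]
#' @param mk801 MK-801 concentration, uM
#' @return named occupancy vector (D, R, O, B) summing to 1
#' @export
steady_state <- function(rates, mk801 = 0) {
  stopifnot(is_rate_set(rates))
  if (!is.numeric(mk801) || length(mk801) != 1L || mk801 < 0) {
    stop("mk801 must be a single number >= 0", call. = FALSE)
  }
  if (rates$k_r == 0 || rates$k_c == 0) {
    stop("degenerate scheme: k_r and k_c must be > 0 for a stationary state",
         call. = FALSE)
  }
  if (mk801 > 0 && rates$k_u == 0 && rates$k_b > 0 && rates$k_o > 0) {
    out <- c(D = 0, R = 0, O = 0, B = 1)
    attr(out, "absorbing") <- TRUE
    return(out)
  }
  rD <- rates$k_d / rates$k_r
  rO <- rates$k_o / rates$k_c
  rB <- if (mk801 > 0 && rates$k_u > 0) rO * rates$k_b * mk801 / rates$k_u else 0
  denom <- 1 + rD + rO + rB
  out <- c(D = rD, R = 1, O = rO, B = rB) / denom
  attr(out, "absorbing") <- FALSE
  out
}

#' Microscopic open probability from opening and closing rates
#'
#' `P_o = 100 * k_o / (k_o + k_c)`, in percent.
#'
#' @param k_o opening rate, 1/s (>= 0)
#' @param k_c closing rate, 1/s (> 0)
#' @return open probability in percent, in `[0, 100)`
#' @export
#' @examples
#' open_probability(27.8, 200)  # ~12.2
open_probability <- function(k_o, k_c) {
  if (!is.numeric(k_o) || any(k_o < 0)) stop("k_o must be >= 0", call. = FALSE)
  if (!is.numeric(k_c) || any(k_c <= 0)) stop("k_c must be > 0", call. = FALSE)
  100 * k_o / (k_o + k_c)
}

#' Predicted NMDAR activity in a heterozygous carrier
#'
#' For a heterozygous carrier of a GluN2B missense variant, random assembly of
#' the two GluN2B copies into diheteromeric receptors gives 25% receptors with
#' two wild-type subunits, 50% with one mutant subunit, and 25% with two
#' mutant subunits. Mixed receptors are assigned the wild-type open
#' probability (recessive), the mean of the two (independent), or the mutant
#' open probability (dominant). The returned value is the population activity
#' relative to an all-wild-type population, in percent.
#'
#' @param po_wt wild-type open probability, percent (0-100, > 0)
#' @param po_mut double-mutant open probability, percent (0-100)
#' @param mode one of "recessive", "independent", "dominant"
#' @return percent of healthy (all-WT) activity
#' @export
#' @examples
#' mendelian_activity(10, 1, "recessive")   # 77.5
#' mendelian_activity(10, 1, "independent") # 55
#' mendelian_activity(10, 1, "dominant")    # 32.5
mendelian_activity <- function(po_wt, po_mut,
                               mode = c("recessive", "independent", "dominant")) {
  mode <- match.arg(mode)
  for (v in c(po_wt, po_mut)) {
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v < 0 || v > 100) {
      stop("open probabilities must be single values in [0, 100]", call. = FALSE)
    }
  }
  if (po_wt == 0) stop("po_wt must be > 0 to define relative activity", call. = FALSE)
  po_mixed <- switch(mode,
                     recessive = po_wt,
                     independent = (po_wt + po_mut) / 2,
                     dominant = po_mut)
  total <- 0.25 * po_wt + 0.5 * po_mixed + 0.25 * po_mut
  100 * total / po_wt
}
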