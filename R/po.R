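# Step 2 of the open-probability procedure: fit the onset of MK-801 block
# with the four-state scheme, k_d/k_r fixed from step 1, k_c fixed at
# 200 /s, k_b fixed at 25 /(uM s), k_o free (optionally k_u free), and
# report P_o = 100 k_o / (k_o + k_c).

# Locate the control (glutamate-only) and MK-801 epochs in a trace protocol.
find_po_epochs <- function(trace) {
  if (is.null(trace$protocol)) {
    stop("trace has no protocol; cannot locate the MK-801 epoch", call. = FALSE)
  }
  ep <- trace$protocol$epochs
  mk_i <- which(ep$glutamate > 0 & ep$mk801 > 0)
  if (length(mk_i) == 0L) stop("protocol contains no glutamate + MK-801 epoch", call. = FALSE)
  mk_i <- mk_i[1]
  ctl_i <- which(ep$glutamate > 0 & ep$mk801 == 0 & ep$t_end <= ep$t_start[mk_i] + 1e-12)
  if (length(ctl_i) == 0L) {
    stop("protocol contains no control (glutamate-only) epoch before MK-801",
         call. = FALSE)
  }
  list(control = utils::tail(ctl_i, 1L), mk = mk_i, epochs = ep)
}

# Model open occupancy over the MK-801 epoch for a candidate rate set.
# Initial condition: stationary occupancies of the drug-free three-state
# sub-scheme (the cell has equilibrated in glutamate before MK-801 arrives);
# the effective MK-801 concentration rises from 0 through the exchange filter.
po_model_curve <- function(k_d, k_r, k_o, k_c, k_b, k_u, mk, exchange_tau,
                           t_rel) {
  rts <- rate_set(k_d, k_r, k_o, k_c, k_b = k_b, k_u = k_u)
  p0 <- steady_state(rts, 0)
  segs <- data.frame(t_start = 0, t_end = t_rel[length(t_rel)] + 1e-9,
                     mk801 = mk, glutamate = 1000)
  res <- sim_core(rts, segs, exchange_tau, t_rel, p0 = as.numeric(p0), c0 = 0)
  res$p[3, ]
}

#' Fit open probability from the onset of MK-801 block
#'
#' Fits the current recorded during the glutamate + MK-801 epoch with the
#' four-state D-R-O-B scheme: `k_d` and `k_r` are fixed at the step-1 values,
#' `k_c` at 200 /s (an arbitrary anchor: only the ratio k_o/k_c is
#' constrained in the slow-block regime), `k_b` at 25 /(uM s); the opening
#' rate `k_o` and the current scale are free. Block is treated as
#' irreversible (`k_u = 0`). The open probability is reported as
#' `P_o = 100 k_o/(k_o + k_c)`.
#'
#' @param trace a [current_trace()] whose protocol contains a glutamate-only
#'   epoch followed by a glutamate + MK-801 epoch
#' @param desens a `desens_fit` from [analyze_desensitization()] on the same
#'   cell's control response
#' @param k_c closing rate, 1/s (fixed)
#' @param k_b MK-801 blocking rate, 1/(uM s) (fixed)
#' @param scale_mode `"free"` fits the current scale by least squares;
#'   `"pinned"` ties it to the pre-MK-801 steady-state current
#' @return object of class `po_fit`: k_o, P_o (percent), k_u, scale,
#'   residual_rmse, converged, config_used
#' @export
fit_po <- function(trace, desens, k_c = 200, k_b = 25,
                   scale_mode = c("free", "pinned")) {
  fit_po_impl(trace, desens, k_c, k_b, match.arg(scale_mode), ku_free = FALSE)
}

#' Fit open probability allowing MK-801 unbinding
#'
#' As [fit_po()], but the unblocking rate `k_u` is a free parameter in
#' addition to `k_o` and the scale. Used for receptors whose MK-801 block is
#' appreciably reversible, where a steady residual current persists under
#' prolonged MK-801 and reflects the block/unblock balance.
#'
#' @inheritParams fit_po
#' @return a `po_fit`; `boundary_warning` is set if the fitted k_u hits the
#'   upper search bound
#' @export
fit_po_with_unblock <- function(trace, desens, k_c = 200, k_b = 25,
                                scale_mode = c("free", "pinned")) {
  fit_po_impl(trace, desens, k_c, k_b, match.arg(scale_mode), ku_free = TRUE)
}

fit_po_impl <- function(trace, desens, k_c, k_b, scale_mode, ku_free) {
  stopifnot(is_current_trace(trace), inherits(desens, "desens_fit"))
  if (k_c <= 0 || k_b <= 0) stop("k_c and k_b must be > 0", call. = FALSE)
  loc <- find_po_epochs(trace)
  ep <- loc$epochs
  mk <- ep$mk801[loc$mk]
  a <- ep$t_start[loc$mk]; b <- ep$t_end[loc$mk]
  sel <- trace$time >= a & trace$time <= b
  t_rel <- trace$time[sel] - a
  i_obs <- trace$current[sel]
  exch <- trace$protocol$exchange_tau
  k_d <- desens$k_d
  k_r <- if (is.na(desens$k_r)) 1e6 else desens$k_r  # non-desensitizing: D pool unused

  # pre-MK steady-state current for the pinned-scale mode
  ctl_b <- ep$t_end[loc$control]
  pre_idx <- trace$time >= ctl_b - 0.2 & trace$time <= ctl_b
  i_pre <- abs(mean(trace$current[pre_idx]))

  obj <- function(log_ko, log_ku = -Inf) {
    ko <- exp(log_ko)
    ku <- if (ku_free) exp(log_ku) else 0
    po <- po_model_curve(k_d, k_r, ko, k_c, k_b, ku, mk, exch, t_rel)
    s <- if (scale_mode == "free") {
      denom <- sum(po^2)
      if (denom <= 0) return(list(rss = sum(i_obs^2), scale = 0))
      max(0, -sum(po * i_obs) / denom)
    } else {
      po_ss <- steady_state(rate_set(k_d, k_r, ko, k_c), 0)[["O"]]
      if (po_ss <= 0) return(list(rss = sum(i_obs^2), scale = 0))
      i_pre / po_ss
    }
    list(rss = sum((i_obs + s * po)^2), scale = s)
  }

  lo <- log(1e-3); hi <- log(1e4)
  if (!ku_free) {
    grid <- seq(lo, hi, length.out = 25)
    rss_grid <- vapply(grid, function(g) obj(g)$rss, numeric(1))
    j <- which.min(rss_grid)
    bracket <- c(grid[max(1, j - 1)], grid[min(length(grid), j + 1)])
    opt <- stats::optimize(function(g) obj(g)$rss, interval = bracket,
                           tol = 1e-10)
    log_ko <- opt$minimum
    final <- obj(log_ko)
    init_rss <- rss_grid[j]
    k_u_hat <- 0
    boundary <- FALSE
  } else {
    ku_hi <- log(1e3)
    # seed k_o from a coarse irreversible scan, then explore k_u from
    # well-separated magnitudes
    grid <- seq(lo, hi, length.out = 25)
    rss_grid <- vapply(grid, function(g) obj(g)$rss, numeric(1))
    ko_seed <- grid[which.min(rss_grid)]
    starts <- rbind(cbind(ko_seed, log(c(1e-4, 0.1, 10))),
                    c(log(1), log(1)))
    best <- NULL
    init_rss <- min(rss_grid)
    for (s_i in seq_len(nrow(starts))) {
      st <- as.numeric(starts[s_i, ])
      init_rss <- min(init_rss, obj(st[1], st[2])$rss)
      o <- stats::optim(st, function(p) obj(p[1], p[2])$rss,
                        method = "L-BFGS-B",
                        lower = c(lo, log(1e-8)), upper = c(hi, ku_hi),
                        control = list(factr = 1e4))
      if (is.null(best) || o$value < best$value) best <- o
    }
    log_ko <- best$par[1]
    k_u_hat <- exp(best$par[2])
    boundary <- best$par[2] > ku_hi - 1e-3
    if (boundary) warning("fitted k_u is at the upper search bound")
    final <- obj(best$par[1], best$par[2])
  }
  k_o_hat <- exp(log_ko)

  # convergence diagnostics: did the current actually decay under MK-801,
  # and did the optimizer improve on its starting point?
  n_seg <- max(10L, floor(length(i_obs) * 0.05))
  drop_obs <- 1 - abs(mean(utils::tail(i_obs, n_seg))) /
    max(abs(mean(utils::head(i_obs, n_seg))), 1e-12)
  converged <- final$rss <= init_rss + 1e-12 && drop_obs > 0.02 &&
    log_ko > lo + 1e-6 && log_ko < hi - 1e-6
  if (drop_obs <= 0.02) {
    warning("current does not decay under MK-801; P_o estimate unreliable")
  }

  structure(list(
    k_o = k_o_hat,
    P_o = open_probability(k_o_hat, k_c),
    k_u = k_u_hat,
    scale = final$scale,
    residual_rmse = sqrt(final$rss / length(i_obs)),
    converged = converged,
    boundary_warning = if (ku_free) boundary else FALSE,
    config_used = list(k_c = k_c, k_b = k_b, mk801 = mk,
                       scale_mode = scale_mode, ku_free = ku_free)
  ), class = "po_fit")
}

#' @export
print.po_fit <- function(x, ...) {
  cat("<po_fit>\n")
  cat(sprintf("  k_o = %.4g /s   P_o = %.3g %%   k_u = %.3g /s\n",
              x$k_o, x$P_o, x$k_u))
  cat(sprintf("  scale = %.4g pA   rmse = %.3g pA   converged: %s\n",
              x$scale, x$residual_rmse, x$converged))
  invisible(x)
}

#' Run the full two-step open-probability procedure
#'
#' Step 1: [analyze_desensitization()] on the control (glutamate-only)
#' response. Step 2: [fit_po()] (or [fit_po_with_unblock()] when
#' `ku_free = TRUE`) on the MK-801 epoch with k_d, k_r fixed at the step-1
#' values.
#'
#' @param control_trace trace holding the control response; for a combined
#'   protocol (glutamate epoch followed by glutamate + MK-801) the same trace
#'   carries both steps and `mk_trace` can be omitted
#' @param mk_trace trace holding the MK-801 epoch; defaults to `control_trace`
#' @param ku_free allow MK-801 unbinding in step 2
#' @param ... passed to [fit_po()] / [fit_po_with_unblock()]
#' @return list with elements `desens` (a `desens_fit`) and `po` (a `po_fit`)
#' @export
two_step_pipeline <- function(control_trace, mk_trace = NULL, ku_free = FALSE,
                              ...) {
  if (is.null(mk_trace)) mk_trace <- control_trace
  desens <- analyze_desensitization(control_trace)
  po <- if (ku_free) {
    fit_po_with_unblock(mk_trace, desens, ...)
  } else {
    fit_po(mk_trace, desens, ...)
  }
  list(desens = desens, po = po)
}
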