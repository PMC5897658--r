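#' One epoch of an application protocol
#'
#' @param t_start,t_end epoch boundaries, s
#' @param glutamate,glycine,mk801,steroid concentrations, uM
#' @param mg Mg2+ concentration, mM
#' @return one-row data.frame
#' @export
protocol_epoch <- function(t_start, t_end, glutamate = 0, glycine = 0,
                           mk801 = 0, mg = 0, steroid = 0) {
  data.frame(t_start = t_start, t_end = t_end, glutamate = glutamate,
             glycine = glycine, mk801 = mk801, mg = mg, steroid = steroid)
}

#' Solution-application protocol
#'
#' An ordered set of non-overlapping epochs, each with nominal concentrations
#' of glutamate, glycine, MK-801 (uM), Mg2+ (mM) and steroid (uM), plus the
#' solution-exchange time constant. Nominal concentrations relax toward their
#' epoch targets with first-order kinetics (time constant `exchange_tau`);
#' `exchange_tau = 0` gives instantaneous steps. The whole-cell exchange time
#' constant for dish-attached cells is about 12 ms.
#'
#' @param epochs data.frame with columns t_start, t_end, glutamate, glycine,
#'   mk801, mg, steroid (rows from [protocol_epoch()] can be `rbind`-ed)
#' @param exchange_tau solution-exchange time constant, s (>= 0)
#' @return object of class `application_protocol`
#' @export
#' @examples
#' application_protocol(rbind(
#'   protocol_epoch(0, 10, glutamate = 1000, glycine = 30),
#'   protocol_epoch(10, 40, glutamate = 1000, glycine = 30, mk801 = 1)
#' ), exchange_tau = 0.012)
application_protocol <- function(epochs, exchange_tau = 0.012) {
  need <- c("t_start", "t_end", "glutamate", "glycine", "mk801", "mg", "steroid")
  if (!is.data.frame(epochs) || !all(need %in% names(epochs))) {
    stop("epochs must be a data.frame with columns ",
         paste(need, collapse = ", "), call. = FALSE)
  }
  if (nrow(epochs) == 0L) stop("protocol must contain at least one epoch", call. = FALSE)
  epochs <- epochs[order(epochs$t_start), need]
  if (any(epochs$t_end <= epochs$t_start)) {
    stop("every epoch must have t_end > t_start", call. = FALSE)
  }
  if (nrow(epochs) > 1L &&
      any(epochs$t_start[-1L] < epochs$t_end[-nrow(epochs)] - 1e-12)) {
    stop("epochs must not overlap", call. = FALSE)
  }
  if (any(as.matrix(epochs[, need[-(1:2)]]) < 0)) {
    stop("concentrations must be >= 0", call. = FALSE)
  }
  if (!is.numeric(exchange_tau) || length(exchange_tau) != 1L || exchange_tau < 0) {
    stop("exchange_tau must be a single number >= 0", call. = FALSE)
  }
  rownames(epochs) <- NULL
  structure(list(epochs = epochs, exchange_tau = exchange_tau),
            class = "application_protocol")
}

#' @export
print.application_protocol <- function(x, ...) {
  cat(sprintf("<application_protocol>  %d epoch(s), exchange_tau = %g s\n",
              nrow(x$epochs), x$exchange_tau))
  print(x$epochs)
  invisible(x)
}

is_protocol <- function(x) inherits(x, "application_protocol")

#' Time of glutamate onset in a protocol
#' @param protocol an [application_protocol()]
#' @return start time (s) of the first epoch with glutamate > 0, or NA
#' @keywords internal
glutamate_onset <- function(protocol) {
  i <- which(protocol$epochs$glutamate > 0)
  if (length(i) == 0L) return(NA_real_)
  protocol$epochs$t_start[min(i)]
}

#' Tile a protocol into contiguous segments with target concentrations
#'
#' Gaps between epochs (and after the last epoch, up to `t_max`) become wash
#' segments with all concentrations zero.
#'
#' @return data.frame t_start, t_end, mk801, glutamate
#' @keywords internal
protocol_segments <- function(protocol, t_min, t_max) {
  ep <- protocol$epochs
  segs <- list()
  cur <- t_min
  for (i in seq_len(nrow(ep))) {
    if (ep$t_end[i] <= cur) next
    if (ep$t_start[i] > cur) {
      segs[[length(segs) + 1L]] <- data.frame(
        t_start = cur, t_end = ep$t_start[i], mk801 = 0, glutamate = 0)
      cur <- ep$t_start[i]
    }
    segs[[length(segs) + 1L]] <- data.frame(
      t_start = max(cur, ep$t_start[i]), t_end = ep$t_end[i],
      mk801 = ep$mk801[i], glutamate = ep$glutamate[i])
    cur <- ep$t_end[i]
  }
  if (cur < t_max) {
    segs[[length(segs) + 1L]] <- data.frame(
      t_start = cur, t_end = t_max, mk801 = 0, glutamate = 0)
  }
  out <- do.call(rbind, segs)
  out[out$t_end > out$t_start, , drop = FALSE]
}

#' Serialize an application protocol to JSON
#' @param protocol an [application_protocol()]
#' @param path file path to write
#' @return `path`, invisibly
#' @export
write_protocol <- function(protocol, path) {
  stopifnot(is_protocol(protocol))
  jsonlite::write_json(list(epochs = protocol$epochs,
                            exchange_tau = protocol$exchange_tau),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read an application protocol from JSON
#' @param path file written by [write_protocol()]
#' @return an [application_protocol()]
#' @export
read_protocol <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(x$epochs)) stop("protocol JSON must contain 'epochs'", call. = FALSE)
  application_protocol(as.data.frame(x$epochs),
                       exchange_tau = if (is.null(x$exchange_tau)) 0 else x$exchange_tau)
}
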