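#' Kinetic rate constants of the D-R-O-B scheme
#'
#' Constructs the set of rate constants governing the four-state scheme
#' used throughout the package:
#'
#' \preformatted{  D <--(k_r / k_d)--> R <--(k_o / k_c)--> O <--(k_b[MK] / k_u)--> B}
#'
#' where D is the desensitized, R the closed (resting, doubly liganded),
#' O the open, and B the MK-801-blocked state. Agonist binding steps are not
#' represented: at saturating glutamate the receptor population is almost
#' exclusively doubly liganded, so the scheme starts from R.
#'
#' @param k_d desensitization rate, 1/s (R -> D)
#' @param k_r resensitization rate, 1/s (D -> R)
#' @param k_o channel opening rate, 1/s (R -> O)
#' @param k_c channel closing rate, 1/s (O -> R); conventionally fixed at
#'   200/s when estimating open probability from MK-801 block kinetics
#' @param k_b MK-801 blocking rate, 1/(uM s); default 25
#' @param k_u MK-801 unblocking rate, 1/s; 0 encodes irreversible block
#' @return an object of class `rate_set`
#' @seealso [simulate_occupancies()], [steady_state()], [open_probability()]
#' @export
#' @examples
#' rate_set(k_d = 0.17, k_r = 0.69, k_o = 27.8, k_c = 200)
rate_set <- function(k_d, k_r, k_o, k_c, k_b = 25, k_u = 0) {
  r <- list(k_d = k_d, k_r = k_r, k_o = k_o, k_c = k_c, k_b = k_b, k_u = k_u)
  for (nm in names(r)) {
    v <- r[[nm]]
    if (!is.numeric(v) || length(v) != 1L || is.na(v)) {
      stop("rate '", nm, "' must be a single finite number", call. = FALSE)
    }
    if (v < 0) stop("rate '", nm, "' must be >= 0 (got ", v, ")", call. = FALSE)
  }
  structure(r, class = "rate_set")
}

#' @export
print.rate_set <- function(x, ...) {
  cat("<rate_set>  (1/s except k_b in 1/(uM s))\n")
  cat(sprintf("  k_d = %g  k_r = %g  k_o = %g  k_c = %g  k_b = %g  k_u = %g\n",
              x$k_d, x$k_r, x$k_o, x$k_c, x$k_b, x$k_u))
  invisible(x)
}

is_rate_set <- function(x) inherits(x, "rate_set")

#' Generator matrix of the scheme at a fixed MK-801 concentration
#'
#' Builds the 4x4 infinitesimal generator for state order (D, R, O, B) so that
#' dp/dt = A p. Column sums are zero (probability conservation).
#'
#' @param rates a [rate_set()]
#' @param mk801 MK-801 concentration, uM
#' @return 4x4 numeric matrix
#' @keywords internal
scheme_generator <- function(rates, mk801 = 0) {
  kbm <- rates$k_b * mk801
  matrix(c(
    -rates$k_r,  rates$k_d,            0,          0,
     rates$k_r, -(rates$k_d + rates$k_o), rates$k_c, 0,
     0,          rates$k_o,  -(rates$k_c + kbm), rates$k_u,
     0,          0,            kbm,    -rates$k_u
  ), nrow = 4, byrow = TRUE,
  dimnames = list(c("D", "R", "O", "B"), c("D", "R", "O", "B")))
}

#' Serialize a rate set to JSON
#'
#' Field names match the `rate_set` constructor exactly, so the files
#' round-trip through [read_rate_set()].
#'
#' @param rates a [rate_set()]
#' @param path file path to write
#' @return `path`, invisibly
#' @export
write_rate_set <- function(rates, path) {
  stopifnot(is_rate_set(rates))
  jsonlite::write_json(unclass(rates), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a rate set from a JSON file
#'
#' @param path file written by [write_rate_set()] (or any JSON object with
#'   fields k_d, k_r, k_o, k_c and optionally k_b, k_u)
#' @return a [rate_set()]
#' @export
read_rate_set <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  need <- c("k_d", "k_r", "k_o", "k_c")
  if (!all(need %in% names(x))) {
    stop("rate-set JSON must contain fields ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  rate_set(x$k_d, x$k_r, x$k_o, x$k_c,
           k_b = if (is.null(x$k_b)) 25 else x$k_b,
           k_u = if (is.null(x$k_u)) 0 else x$k_u)
}
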