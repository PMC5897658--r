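# Trace file format: two-column CSV (time_s, current_pA) with a sidecar
# JSON metadata record at <path>.json. Text formats keep fixtures diffable.

#' Write a current trace to CSV + sidecar JSON
#'
#' The data file has header `time_s,current_pA`; the sidecar (at
#' `<path>.json`) records sampling_rate, holding_potential_mV, cell_id,
#' construct, and the application protocol.
#'
#' @param trace a [current_trace()]
#' @param path CSV file path
#' @return `path`, invisibly
#' @export
write_trace <- function(trace, path) {
  stopifnot(is_current_trace(trace))
  df <- data.frame(time_s = trace$time, current_pA = trace$current)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  meta <- list(sampling_rate = trace$sampling_rate,
               holding_potential_mV = trace$holding_potential,
               cell_id = trace$cell_id,
               construct = trace$construct)
  if (!is.null(trace$protocol)) {
    meta$protocol <- list(epochs = trace$protocol$epochs,
                          exchange_tau = trace$protocol$exchange_tau)
  }
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, null = "null", na = "null")
  invisible(path)
}

#' Read a current trace from CSV + sidecar JSON
#'
#' @param path CSV file with header `time_s,current_pA`; the sidecar JSON is
#'   looked up at `<path>.json` (a missing sidecar yields a protocol-less
#'   trace with a warning)
#' @return a [current_trace()]
#' @export
read_trace <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  need <- c("time_s", "current_pA")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols)) {
    stop("trace CSV is missing column(s): ",
         paste(missing_cols, collapse = ", "),
         " (header must be 'time_s,current_pA')", call. = FALSE)
  }
  if (nrow(df) < 2L) stop("trace must contain at least two rows", call. = FALSE)
  side <- paste0(path, ".json")
  meta <- NULL
  if (file.exists(side)) {
    meta <- jsonlite::read_json(side, simplifyVector = TRUE)
  } else {
    warning("no sidecar metadata at ", side, "; returning protocol-less trace")
  }
  prot <- NULL
  if (!is.null(meta$protocol)) {
    prot <- application_protocol(as.data.frame(meta$protocol$epochs),
                                 exchange_tau = meta$protocol$exchange_tau)
  }
  scalar_or <- function(x, default) {
    if (is.null(x) || length(x) == 0L || is.na(x[1])) default else x[1]
  }
  current_trace(df$time_s, df$current_pA,
                sampling_rate = if (is.null(meta$sampling_rate)) NULL else meta$sampling_rate,
                protocol = prot,
                holding_potential = scalar_or(meta$holding_potential_mV, -60),
                cell_id = scalar_or(meta$cell_id, NA_character_),
                construct = scalar_or(meta$construct, NA_character_))
}

# Serialize a numeric data.frame as TSV with 10 significant digits.
write_result_tsv <- function(df, path) {
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], function(x) signif(x, 10))
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
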