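# Batch driver: run analysis stages over sets of trace files and collect
# per-cell result tables plus a reproducibility manifest.

#' Run a configured analysis pipeline
#'
#' Executes the requested stages over the listed inputs and writes one TSV
#' result table per stage plus a JSON manifest (package version, seed,
#' config hash, per-item status). Stage errors are recorded per item and do
#' not abort the run (fail-soft); the returned bundle carries a nonzero
#' `exit_status` if any item failed.
#'
#' Supported stages and their inputs:
#' \describe{
#'   \item{desens}{`traces`: CSV paths; runs [analyze_desensitization()]}
#'   \item{po}{`traces`: CSV paths (combined control + MK-801 protocol);
#'     runs [two_step_pipeline()]; options `ku_free`, `k_c`, `k_b`,
#'     `scale_mode`}
#'   \item{hill}{`files`: two-column CSVs (conc, response); option `mode`}
#'   \item{woodhull}{`pairs`: list of `(no_mg, mg, mg_mM)` CSV path records}
#'   \item{synaptic}{`pairs`: list of `(control, steroid)` CSV path records}
#'   \item{idealize}{`traces`: CSV paths; options `baseline`, `open_level`,
#'     `dead_time`, `fc`}
#' }
#'
#' @param config a list, or path to a JSON file, with fields `seed`
#'   (optional) and `stages` (named list keyed by stage name)
#' @param out_dir output directory for TSVs and the manifest
#' @return results bundle (list of per-stage data.frames, `exit_status`,
#'   `manifest`), invisibly
#' @export
run_pipeline <- function(config, out_dir = ".") {
  if (is.character(config)) config <- jsonlite::read_json(config, simplifyVector = FALSE)
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  seed <- if (!is.null(config$seed)) as.integer(config$seed) else NA_integer_
  if (!is.na(seed)) set.seed(seed)
  cfg_json <- jsonlite::toJSON(config, auto_unbox = TRUE, digits = NA)
  cfg_file <- tempfile(); writeLines(cfg_json, cfg_file)
  cfg_hash <- unname(tools::md5sum(cfg_file)); unlink(cfg_file)

  results <- list()
  status <- list()
  failed <- 0L

  run_items <- function(items, fun) {
    rows <- list(); st <- list()
    for (nm in seq_along(items)) {
      it <- items[[nm]]
      label <- if (is.character(it) && length(it) == 1L) it else paste0("item", nm)
      res <- tryCatch(suppressWarnings(list(ok = TRUE, row = fun(it))),
                      error = function(e) list(ok = FALSE, msg = conditionMessage(e)))
      if (res$ok) {
        rows[[length(rows) + 1L]] <- res$row
        st[[label]] <- "ok"
      } else {
        st[[label]] <- paste("error:", res$msg)
        failed <<- failed + 1L
      }
    }
    list(table = if (length(rows)) do.call(rbind, rows) else NULL, status = st)
  }

  stages <- config$stages
  for (stage in names(stages)) {
    sc <- stages[[stage]]
    out <- switch(stage,
      desens = run_items(sc$traces, function(p) {
        tr <- read_trace(p)
        d <- analyze_desensitization(tr)
        data.frame(cell_id = tr$cell_id, I_P_pA = d$I_P, I_SS_pA = d$I_SS,
                   D = d$D, tau_d_s = d$tau_d, k_d_per_s = d$k_d,
                   k_r_per_s = d$k_r, fit_rmse_pA = d$fit_rmse)
      }),
      po = run_items(sc$traces, function(p) {
        tr <- read_trace(p)
        r <- two_step_pipeline(tr,
                               ku_free = isTRUE(sc$ku_free),
                               k_c = if (is.null(sc$k_c)) 200 else sc$k_c,
                               k_b = if (is.null(sc$k_b)) 25 else sc$k_b,
                               scale_mode = if (is.null(sc$scale_mode)) "free" else sc$scale_mode)
        data.frame(cell_id = tr$cell_id, D = r$desens$D,
                   tau_d_s = r$desens$tau_d, k_d_per_s = r$desens$k_d,
                   k_r_per_s = r$desens$k_r, k_o_per_s = r$po$k_o,
                   P_o_percent = r$po$P_o, k_u_per_s = r$po$k_u,
                   converged = r$po$converged)
      }),
      hill = run_items(sc$files, function(p) {
        df <- utils::read.csv(p)
        f <- fit_hill(df[[1]], df[[2]],
                      mode = if (is.null(sc$mode)) "agonist" else sc$mode)
        data.frame(file = p, EC50_uM = f$EC50, h = f$h, I_max = f$I_max,
                   se_EC50_uM = f$se_EC50, se_h = f$se_h)
      }),
      woodhull = run_items(sc$pairs, function(it) {
        f <- fit_woodhull(utils::read.csv(it$no_mg), utils::read.csv(it$mg),
                          mg = it$mg_mM)
        data.frame(no_mg = it$no_mg, V_rev_mV = f$V_rev, Kd0_mM = f$a,
                   delta = f$delta, unreliable = f$unreliable)
      }),
      synaptic = run_items(sc$pairs, function(it) {
        s <- synaptic_summary(read_trace(it$control), read_trace(it$steroid))
        data.frame(control = it$control,
                   tau_control_s = s$control$tau_report,
                   tau_steroid_s = s$steroid$tau_report,
                   potentiation_percent = s$potentiation,
                   deceleration = s$deceleration,
                   charge_transfer = s$charge_transfer)
      }),
      idealize = run_items(sc$traces, function(p) {
        tr <- read_trace(p)
        if (!is.null(sc$fc)) tr <- filter_trace(tr, sc$fc)
        ev <- idealize_half_threshold(
          tr,
          baseline = sc$baseline, open_level = sc$open_level,
          dead_time = if (is.null(sc$dead_time)) 446e-6 else sc$dead_time)
        data.frame(file = p, n_open = sum(ev$state == "open"),
                   open_time_s = sum(ev$duration[ev$state == "open"]),
                   P_o_percent = single_channel_po(ev))
      }),
      stop("unknown pipeline stage: ", stage, call. = FALSE)
    )
    results[[stage]] <- out$table
    status[[stage]] <- out$status
    if (!is.null(out$table)) {
      write_result_tsv(out$table, file.path(out_dir, paste0(stage, ".tsv")))
    }
  }

  manifest <- list(
    package = "channelkit",
    version = as.character(utils::packageVersion("channelkit")),
    seed = seed,
    config_md5 = cfg_hash,
    status = status
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  bundle <- list(results = results, exit_status = as.integer(failed > 0L),
                 manifest = manifest)
  invisible(bundle)
}
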