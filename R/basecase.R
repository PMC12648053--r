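# Base-case orchestration and report writers.

#' Run the base-case comparison
#'
#' Runs the lifetime cohort model for both diet strategies under the same
#' parameter set and compares them.
#'
#' @param params A `ckdcea_params` object (default: [default_parameters()]).
#' @param perspective `"nhs"` or `"societal"`; defaults to the settings value.
#' @return A `ckdcea_run`: list with `lpd` and `svlpd` outcome summaries,
#'   `cea` (the incremental comparison), `traces` and the perspective.
#' @export
run_base_case <- function(params = default_parameters(), perspective = NULL) {
  if (is.null(perspective)) perspective <- params$settings$perspective$value
  perspective <- match.arg(perspective, c("nhs", "societal"))
  tr_lpd <- run_cohort(params, "lpd")
  tr_svlpd <- run_cohort(params, "svlpd")
  out_lpd <- strategy_outcomes(tr_lpd, params, "lpd", perspective)
  out_svlpd <- strategy_outcomes(tr_svlpd, params, "svlpd", perspective)
  structure(list(
    lpd = out_lpd, svlpd = out_svlpd,
    cea = compare_strategies(out_lpd, out_svlpd),
    traces = list(lpd = tr_lpd, svlpd = tr_svlpd),
    perspective = perspective
  ), class = "ckdcea_run")
}

#' @export
print.ckdcea_run <- function(x, ...) {
  cat(sprintf("<ckdcea_run> LPD vs s-VLPD, %s perspective\n", x$perspective))
  print(base_case_table(x), row.names = FALSE)
  cat(sprintf("verdict: %s\n", x$cea$verdict))
  invisible(x)
}

#' Base-case results table
#'
#' Lays the run out as the standard cost-utility report: survival, per-state
#' time, QALYs, itemized costs and totals, with LPD, s-VLPD and delta columns.
#'
#' @param run A `ckdcea_run`.
#' @return Data frame with columns `outcome`, `lpd`, `svlpd`, `delta`.
#' @export
base_case_table <- function(run) {
  stopifnot(inherits(run, "ckdcea_run"))
  a <- run$lpd; b <- run$svlpd
  items <- union(names(a$cost_items), names(b$cost_items))
  if (run$perspective == "nhs") items <- setdiff(items, "indirect")
  rows <- rbind(
    data.frame(outcome = c("survival_years", "time_pre_dialysis_years",
                           "time_dialysis_years", "qalys"),
               lpd = c(a$survival_years, a$time_pre_dialysis_years,
                       a$time_dialysis_years, a$qalys),
               svlpd = c(b$survival_years, b$time_pre_dialysis_years,
                         b$time_dialysis_years, b$qalys)),
    data.frame(outcome = paste0("cost_", items),
               lpd = as.numeric(a$cost_items[items]),
               svlpd = as.numeric(b$cost_items[items])),
    data.frame(outcome = "total_cost", lpd = a$total_cost, svlpd = b$total_cost)
  )
  rows$delta <- rows$svlpd - rows$lpd
  rows
}

#' Write run outputs and a reproducibility manifest
#'
#' Writes the results table as TSV and/or JSON plus a `manifest.json`
#' recording the command, configuration path, seed, package version,
#' timestamp and every output file, so any run can be reproduced from its
#' manifest.
#'
#' @param run A `ckdcea_run` (or any object with a `base_case_table`-style
#'   table from `table_fn`).
#' @param out_dir Output directory (created if missing).
#' @param format `"tsv"`, `"json"` or both.
#' @param command Label recorded in the manifest.
#' @param config Configuration path recorded in the manifest (or NA).
#' @param seed Seed recorded in the manifest (or NA).
#' @param prefix File-name prefix.
#' @return Invisibly, the manifest as a list.
#' @export
write_run_outputs <- function(run, out_dir, format = c("tsv", "json"),
                              command = "run", config = NA, seed = NA,
                              prefix = "base_case") {
  format <- match.arg(format, c("tsv", "json"), several.ok = TRUE)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  tab <- base_case_table(run)
  outputs <- character(0)
  if ("tsv" %in% format) {
    f <- file.path(out_dir, paste0(prefix, ".tsv"))
    utils::write.table(tab, f, sep = "\t", quote = FALSE, row.names = FALSE)
    outputs <- c(outputs, f)
  }
  if ("json" %in% format) {
    f <- file.path(out_dir, paste0(prefix, ".json"))
    payload <- list(
      table = tab,
      cea = list(delta_cost = run$cea$delta_cost, delta_qaly = run$cea$delta_qaly,
                 delta_survival = run$cea$delta_survival, verdict = run$cea$verdict,
                 icer = run$cea$icer),
      perspective = run$perspective
    )
    jsonlite::write_json(payload, f, auto_unbox = TRUE, digits = NA, na = "null")
    outputs <- c(outputs, f)
  }
  manifest <- list(command = command, config = config, seed = seed,
                   package_version = as.character(utils::packageVersion("ckdcea")),
                   timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
                   outputs = outputs)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, na = "null")
  invisible(manifest)
}
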