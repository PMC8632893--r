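#' Persist and reload a run
#'
#' A run is stored as plain-text artifacts in a directory: `metadata.json`
#' (configuration, seed, package version), and CSVs `timeseries.csv`,
#' `tools.csv`, `sources.csv`, `trees.csv`, `primates.csv` (plus `bouts.csv`
#' when the bout log was recorded). Column order is fixed by the writing
#' schema and doubles round-trip losslessly, so `read_run(write_run(r, d))`
#' reproduces `r` exactly.
#'
#' @param run A `toolscape_run`.
#' @param dir Output directory (created if missing).
#' @return `write_run()` returns `dir` invisibly; `read_run()` returns a
#'   `toolscape_run`.
#' @export
write_run <- function(run, dir) {
  stopifnot(inherits(run, "toolscape_run"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  cfg <- unclass(run$config)
  cfg$fragment_distribution <- unclass(cfg$fragment_distribution)
  cfg <- cfg[!vapply(cfg, is.null, logical(1))]
  meta <- list(config = cfg, seed = run$seed, n_steps = run$n_steps,
               n_regrow_widened = run$n_regrow_widened,
               package_version = as.character(utils::packageVersion("toolscape")))
  jsonlite::write_json(meta, file.path(dir, "metadata.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  for (nm in c("timeseries", "tools", "sources", "trees", "primates")) {
    readr::write_csv(run[[nm]], file.path(dir, paste0(nm, ".csv")))
  }
  if (!is.null(run$bouts)) {
    readr::write_csv(run$bouts, file.path(dir, "bouts.csv"))
  }
  invisible(dir)
}

#' @rdname write_run
#' @export
read_run <- function(dir) {
  metapath <- file.path(dir, "metadata.json")
  if (!file.exists(metapath)) {
    stop("not a run directory (missing metadata.json): ", dir, call. = FALSE)
  }
  meta <- jsonlite::read_json(metapath, simplifyVector = TRUE)
  cfg <- meta$config
  fd <- cfg$fragment_distribution
  cfg$fragment_distribution <- if (identical(fd$type, "empirical")) {
    fragment_empirical(fd$masses)
  } else {
    fd$type <- NULL
    do.call(fragment_mixture, as.list(fd))
  }
  config <- do.call(sim_config, cfg)

  read_table <- function(nm, col_types) {
    path <- file.path(dir, paste0(nm, ".csv"))
    if (!file.exists(path)) {
      stop("run directory ", dir, " is missing ", nm, ".csv", call. = FALSE)
    }
    tab <- readr::read_csv(path, col_types = col_types)
    probs <- readr::problems(tab)
    if (nrow(probs) > 0) {
      stop("malformed ", path, " at line ", probs$row[1], ": ",
           probs$expected[1], " expected", call. = FALSE)
    }
    tab
  }
  run <- structure(
    list(config = config, seed = as.integer(meta$seed),
         n_steps = as.integer(meta$n_steps),
         timeseries = read_table("timeseries", "iiid"),
         tools = read_table("tools", "iiiiiddiiiili"),
         sources = read_table("sources", "iiii"),
         trees = read_table("trees", "iiiiliii"),
         primates = read_table("primates", "iii"),
         bouts = NULL,
         n_regrow_widened = meta$n_regrow_widened),
    class = "toolscape_run")
  if (file.exists(file.path(dir, "bouts.csv"))) {
    run$bouts <- read_table("bouts", "iiiiidiiiiildc")
  }
  run
}

#' Write sweep outputs
#'
#' Writes `summaries.csv` (one row per run) and `report.json` (the
#' [sweep_statistics()] glance row) for a sweep summary table.
#'
#' @param summaries Output of [run_sweep()].
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
write_sweep <- function(summaries, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  out <- summaries[setdiff(names(summaries), "run")]
  readr::write_csv(out, file.path(dir, "summaries.csv"))
  stats <- sweep_statistics(summaries)
  jsonlite::write_json(as.list(glance(stats)), file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
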