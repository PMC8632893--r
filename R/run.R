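#' Run a complete simulation
#'
#' Executes `config$n_steps` world updates from a fresh world and returns the
#' full run record: the per-interval tool-use-location timeseries, every tool
#' and fragment ever created (with provenance, masses and use counts), the
#' source layer, the full tree history (including dead trees), and the final
#' primate positions. `(config, seed)` fully determines every value.
#'
#' A tool-use location is a live tree with a source or usable tool within
#' `location_radius` (default 3) cells — the places where nut-cracking can
#' actually happen. Its count is recorded every `record_every` steps together
#' with the current maximum displacement of any non-fragment tool from its
#' origin source.
#'
#' @param config A [sim_config()].
#' @param seed Integer seed; defaults to `config$seed`.
#' @param n_steps Run length; defaults to `config$n_steps`.
#' @return A `toolscape_run`: list with `config`, `seed`, `timeseries`,
#'   `tools`, `sources`, `trees`, `primates` tibbles and (if
#'   `config$record_bouts`) a `bouts` log.
#' @examples
#' cfg <- sim_config(width = 60, height = 60, n_primates = 20, n_trees = 40,
#'                   n_sources = 10, n_steps = 500)
#' run <- simulate_run(cfg, seed = 42)
#' run$timeseries[nrow(run$timeseries), ]
#' @export
simulate_run <- function(config, seed = config$seed, n_steps = config$n_steps) {
  stopifnot(inherits(config, "sim_config"))
  if (is.null(seed)) stop("a seed is required (in the config or as `seed`)",
                          call. = FALSE)
  set.seed(as.integer(seed))
  res <- cpp_sim(cfg_for_cpp(config), NULL, as.integer(n_steps),
                 resolve_record_every(config, n_steps),
                 isTRUE(config$record_bouts))
  w <- state_to_world(res$state, config)
  structure(
    list(config = config, seed = as.integer(seed),
         n_steps = as.integer(n_steps),
         timeseries = ts_tibble(res$timeseries),
         tools = w$tools, sources = w$sources, trees = w$trees,
         primates = w$primates,
         bouts = bouts_tibble(res$bouts),
         n_regrow_widened = w$n_regrow_widened),
    class = "toolscape_run")
}

#' @export
print.toolscape_run <- function(x, ...) {
  ts <- x$timeseries
  cat("<toolscape_run> ", x$n_steps, " steps, seed ", x$seed, "\n", sep = "")
  cat("  tools created: ", sum(!x$tools$is_fragment), " (+",
      sum(x$tools$is_fragment), " fragments)\n", sep = "")
  cat("  tool-use locations: ", ts$n_locations[1], " -> ",
      ts$n_locations[nrow(ts)], "\n", sep = "")
  cat("  max displacement from origin: ", max_displacement(x),
      " cells\n", sep = "")
  invisible(x)
}

#' Tidy a simulation run
#'
#' `tidy()` returns the per-tool record table (one row per tool or fragment,
#' with origin provenance, final position, displacement from origin, masses,
#' use count). `glance()` returns a one-row run summary, the same row
#' produced by [summarize_run()].
#'
#' @param x A `toolscape_run`.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.toolscape_run <- function(x, ...) {
  tl <- x$tools
  tl$displacement <- chebyshev_distance(tl$origin_x, tl$origin_y, tl$x, tl$y)
  tl$usable <- tl$mass >= x$config$usable_threshold
  tl
}

#' @rdname tidy.toolscape_run
#' @export
glance.toolscape_run <- function(x, ...) {
  summarize_run(x)
}

#' Summarise a run into one row
#'
#' Computes the headline per-run quantities: maximum displacement of any
#' non-fragment tool from its origin source, tool-use-location counts at the
#' start and end, whether any tool ended more than `location_radius` cells
#' from the *nearest* source (the signature of accumulated transport), the
#' percentage of assemblages containing a usable tool, and basic record
#' counts.
#'
#' @param run A `toolscape_run`.
#' @param run_id Optional identifier carried into the output row.
#' @return One-row tibble.
#' @export
summarize_run <- function(run, run_id = NA_integer_) {
  stopifnot(inherits(run, "toolscape_run"))
  ts <- run$timeseries
  tl <- run$tools
  cfg <- run$config
  nonfrag <- tl[!tl$is_fragment, ]
  beyond <- FALSE
  if (nrow(nonfrag) > 0) {
    d_src <- nearest_source_distance(nonfrag$x, nonfrag$y, run$sources)
    beyond <- any(d_src > cfg$location_radius)
  }
  pct_usable <- NA_real_
  if (nrow(tl) > 0) {
    pct_usable <- pct_assemblages_with_usable(build_assemblages(run))
  }
  exhausted <- nonfrag[nonfrag$mass < cfg$usable_threshold, ]
  tibble::tibble(
    run_id = run_id,
    seed = run$seed,
    n_trees = cfg$n_trees,
    n_sources = cfg$n_sources,
    dynamic_trees = cfg$dynamic_trees,
    n_steps = run$n_steps,
    max_displacement = max_displacement(run),
    n_locations_start = ts$n_locations[1],
    n_locations_end = ts$n_locations[nrow(ts)],
    any_transport_beyond_3 = beyond,
    pct_assemblages_with_usable = pct_usable,
    n_tools = nrow(nonfrag),
    n_fragments = sum(tl$is_fragment),
    median_uses_exhausted = if (nrow(exhausted) > 0)
      stats::median(exhausted$n_uses) else NA_real_)
}
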