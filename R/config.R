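#' Fragment-mass distributions
#'
#' When a pounding tool breaks, the detached fragment's mass is drawn from a
#' right-skewed distribution: chimpanzee nut-cracking observations show most
#' breakage events shed small chips while a minority detach large pieces.
#' `fragment_mixture()` encodes this as a two-component lognormal mixture;
#' `fragment_empirical()` resamples a user-supplied table of observed fragment
#' masses (grams) with replacement, e.g. a field-recorded fragment-size
#' dataset read with [read_fragment_table()].
#'
#' Default mixture parameters give a mean fragment mass of roughly 16 g
#' (90% of draws average ~9 g, 10% average ~84 g), which together with the
#' default initial hammer masses yields expected use-lives between roughly
#' 190 uses (fragility 75) and 770 uses (fragility 0) before exhaustion —
#' the low hundreds (see the methods vignette for the arithmetic).
#'
#' @param p_small Probability a breakage sheds a small fragment.
#' @param small_meanlog,small_sdlog Lognormal parameters of the small
#'   component (grams on the log scale).
#' @param large_meanlog,large_sdlog Lognormal parameters of the large
#'   component.
#' @param masses Numeric vector of observed fragment masses in grams.
#' @return A `fragment_distribution` specification list.
#' @examples
#' fd <- fragment_mixture()
#' fe <- fragment_empirical(c(5, 8, 12, 250))
#' @export
fragment_mixture <- function(p_small = 0.9,
                             small_meanlog = log(6.5), small_sdlog = 0.8,
                             large_meanlog = log(70), large_sdlog = 0.6) {
  stopifnot(p_small >= 0, p_small <= 1, small_sdlog >= 0, large_sdlog >= 0)
  structure(
    list(type = "mixture", p_small = p_small,
         small_meanlog = small_meanlog, small_sdlog = small_sdlog,
         large_meanlog = large_meanlog, large_sdlog = large_sdlog),
    class = "fragment_distribution")
}

#' @rdname fragment_mixture
#' @export
fragment_empirical <- function(masses) {
  masses <- as.numeric(masses)
  if (length(masses) == 0 || anyNA(masses) || any(masses <= 0)) {
    stop("`masses` must be a non-empty vector of positive fragment masses (g)",
         call. = FALSE)
  }
  structure(list(type = "empirical", masses = masses),
            class = "fragment_distribution")
}

#' Read an empirical fragment-mass table
#'
#' Reads a CSV with a `mass` column (grams) and returns a
#' [fragment_empirical()] distribution.
#'
#' @param path Path to a CSV file with a numeric `mass` column.
#' @return A `fragment_distribution`.
#' @export
read_fragment_table <- function(path) {
  tab <- readr::read_csv(path, show_col_types = FALSE)
  if (!"mass" %in% names(tab)) {
    stop("fragment table ", path, " has no `mass` column", call. = FALSE)
  }
  fragment_empirical(tab$mass)
}

#' Simulation configuration
#'
#' Single source of truth for a model run: grid geometry, entity counts,
#' movement and interaction radii, breakage parameters, the initial
#' hammer-mass distribution, tree-turnover settings, run length and seed.
#'
#' Cell coordinates are integer and 0-based: `0 .. width-1` horizontally and
#' `0 .. height-1` vertically. All radii are Chebyshev (chessboard) distances,
#' matching the Moore (8-neighbour) geometry of movement and discard.
#'
#' @param width,height Grid dimensions in cells.
#' @param n_primates Number of primate agents (held at 100 in the reference
#'   experiments).
#' @param n_trees Number of live nut trees, kept constant throughout a run.
#' @param n_sources Number of raw-material sources (fixed positions).
#' @param dynamic_trees If `TRUE`, trees age each step, die at
#'   `tree_lifespan`, and are immediately replaced by a new age-0 tree within
#'   `regrow_radius` cells; if `FALSE` the tree layer is frozen.
#' @param n_steps Run length in time-steps (one step is roughly one
#'   nut-cracking episode).
#' @param tree_lifespan Tree age at death, in steps.
#' @param regrow_radius Chebyshev radius for replacement-tree placement.
#' @param search_radius Radius within which a primate standing by a tree
#'   looks for a source or usable tool.
#' @param interaction_radius Radius defining "at a tree" (1 = the tree's cell
#'   or its eight neighbours).
#' @param location_radius Radius used in the tool-use-location census: a live
#'   tree counts as a tool-use location if a source or usable tool lies within
#'   this distance.
#' @param usable_threshold Minimum usable tool mass in grams; lighter tools
#'   are exhausted and never selected or transported again.
#' @param baseline_break_prob Per-use baseline breakage probability; a tool's
#'   actual probability is `min(1, baseline + fragility/100)`.
#' @param fragility_levels Integer percentage points assigned uniformly at
#'   random to sources; tools inherit the fragility of their origin source.
#' @param initial_mass_mean,initial_mass_sd Normal distribution (grams) of
#'   fresh hammer masses, truncated below at `usable_threshold` by rejection.
#'   Defaults stand in for published Tai Forest Panda-nut hammer masses.
#' @param fragment_distribution A [fragment_mixture()] or
#'   [fragment_empirical()] specification.
#' @param record_every Timeseries recording interval in steps; default every
#'   50 steps for runs longer than 10,000 steps, else every step.
#' @param record_bouts If `TRUE`, log every acquisition-transport-use bout
#'   (memory-heavy; meant for diagnostics on short runs).
#' @param torus If `TRUE`, the grid wraps (sensitivity analyses only); the
#'   default bounded grid represents a forest stand with edges.
#' @param seed Integer RNG seed for the run; may be left `NULL` and supplied
#'   to [simulate_run()] instead.
#' @param preset_trees,preset_sources,preset_primates Optional data frames of
#'   explicit entity placements (columns `x`, `y`, and `fragility` for
#'   sources), used by test scenarios; `NULL` means random placement.
#' @return A validated `sim_config` object (a list).
#' @examples
#' cfg <- sim_config(n_trees = 500, n_sources = 100, n_steps = 1000, seed = 7)
#' cfg$n_trees
#' @export
sim_config <- function(width = 250, height = 250,
                       n_primates = 100,
                       n_trees = 1000,
                       n_sources = 100,
                       dynamic_trees = FALSE,
                       n_steps = 75000,
                       tree_lifespan = 10000,
                       regrow_radius = 10,
                       search_radius = 2,
                       interaction_radius = 1,
                       location_radius = 3,
                       usable_threshold = 2000,
                       baseline_break_prob = 0.25,
                       fragility_levels = c(0L, 25L, 50L, 75L),
                       initial_mass_mean = 5000,
                       initial_mass_sd = 1500,
                       fragment_distribution = fragment_mixture(),
                       record_every = NULL,
                       record_bouts = FALSE,
                       torus = FALSE,
                       seed = NULL,
                       preset_trees = NULL,
                       preset_sources = NULL,
                       preset_primates = NULL) {
  cfg <- list(
    width = as.integer(width), height = as.integer(height),
    n_primates = as.integer(n_primates),
    n_trees = as.integer(n_trees), n_sources = as.integer(n_sources),
    dynamic_trees = isTRUE(dynamic_trees),
    n_steps = as.integer(n_steps),
    tree_lifespan = as.integer(tree_lifespan),
    regrow_radius = as.integer(regrow_radius),
    search_radius = as.integer(search_radius),
    interaction_radius = as.integer(interaction_radius),
    location_radius = as.integer(location_radius),
    usable_threshold = as.numeric(usable_threshold),
    baseline_break_prob = as.numeric(baseline_break_prob),
    fragility_levels = as.integer(fragility_levels),
    initial_mass_mean = as.numeric(initial_mass_mean),
    initial_mass_sd = as.numeric(initial_mass_sd),
    fragment_distribution = fragment_distribution,
    record_every = if (is.null(record_every)) NULL else as.integer(record_every),
    record_bouts = isTRUE(record_bouts),
    torus = isTRUE(torus),
    seed = if (is.null(seed)) NULL else as.integer(seed),
    preset_trees = preset_trees,
    preset_sources = preset_sources,
    preset_primates = preset_primates)
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
}

validate_sim_config <- function(cfg) {
  err <- function(...) stop("invalid configuration: ", ..., call. = FALSE)
  with(cfg, {
    if (width < 1 || height < 1) err("grid dimensions must be positive")
    if (n_primates < 1) err("n_primates must be > 0")
    if (n_trees < 1 || n_sources < 1) err("entity counts must be > 0")
    if (n_steps < 0) err("n_steps must be >= 0")
    if (baseline_break_prob < 0 || baseline_break_prob > 1)
      err("baseline_break_prob must lie in [0, 1]")
    if (any(baseline_break_prob + fragility_levels / 100 < 0))
      err("a fragility level drives the break probability below 0")
    if (usable_threshold <= 0) err("usable_threshold must be > 0")
    if (search_radius < 1) err("search_radius must be >= 1")
    if (interaction_radius < 0 || location_radius < 0 || regrow_radius < 1)
      err("radii must be non-negative (regrow_radius >= 1)")
    if (tree_lifespan < 1) err("tree_lifespan must be >= 1")
    if (n_trees + n_sources > width * height)
      err("n_trees + n_sources exceeds the number of grid cells; ",
          "unique placement is impossible")
    if (initial_mass_sd < 0) err("initial_mass_sd must be >= 0")
    if (initial_mass_sd == 0 && initial_mass_mean < usable_threshold)
      err("initial_mass_mean below usable_threshold with sd = 0: ",
          "every fresh tool would be unusable")
  })
  if (cfg$initial_mass_sd > 0) {
    p_ok <- stats::pnorm(cfg$usable_threshold, cfg$initial_mass_mean,
                         cfg$initial_mass_sd, lower.tail = FALSE)
    if (p_ok < 1e-4) {
      stop("invalid configuration: initial mass distribution lies almost ",
           "entirely below usable_threshold (rejection sampling would stall)",
           call. = FALSE)
    }
    if (p_ok < 0.5) {
      warning("initial_mass_mean is below usable_threshold: more than half ",
              "of mass draws will be rejected", call. = FALSE)
    }
  }
  if (!inherits(cfg$fragment_distribution, "fragment_distribution"))
    stop("fragment_distribution must be created with fragment_mixture() ",
         "or fragment_empirical()", call. = FALSE)
  for (nm in c("preset_trees", "preset_sources", "preset_primates")) {
    ps <- cfg[[nm]]
    if (is.null(ps)) next
    need <- if (nm == "preset_sources") c("x", "y", "fragility") else c("x", "y")
    if (!all(need %in% names(ps)))
      stop(nm, " needs columns ", paste(need, collapse = ", "), call. = FALSE)
    if (any(ps$x < 0 | ps$x >= cfg$width | ps$y < 0 | ps$y >= cfg$height))
      stop(nm, " contains off-grid coordinates", call. = FALSE)
    cfg[[nm]] <- as.list(ps[need])
    cfg[[nm]] <- lapply(cfg[[nm]], as.integer)
  }
  occ <- c(paste(cfg$preset_trees$x, cfg$preset_trees$y),
           paste(cfg$preset_sources$x, cfg$preset_sources$y))
  if (anyDuplicated(occ))
    stop("preset trees/sources must occupy unique cells", call. = FALSE)
  cfg
}

# effective recording interval for a given run length
resolve_record_every <- function(cfg, n_steps = cfg$n_steps) {
  if (!is.null(cfg$record_every)) return(cfg$record_every)
  if (n_steps > 10000) 50L else 1L
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config> ", x$width, "x", x$height, " grid, ",
      x$n_primates, " primates, ", x$n_trees, " trees (",
      if (x$dynamic_trees) "dynamic" else "static", "), ",
      x$n_sources, " sources, ", x$n_steps, " steps\n", sep = "")
  cat("  breakage: baseline ", x$baseline_break_prob, " + fragility/100, ",
      "levels {", paste(x$fragility_levels, collapse = ", "), "}\n", sep = "")
  cat("  hammers: N(", x$initial_mass_mean, ", ", x$initial_mass_sd,
      ") g truncated at ", x$usable_threshold, " g; fragments: ",
      x$fragment_distribution$type, "\n", sep = "")
  if (!is.null(x$seed)) cat("  seed:", x$seed, "\n")
  invisible(x)
}

# keys allowed in a config file, beyond the sim_config() arguments
config_file_keys <- function() {
  setdiff(names(formals(sim_config)),
          c("preset_trees", "preset_sources", "preset_primates",
            "fragment_distribution"))
}

#' Read and write configuration files
#'
#' Configurations persist as YAML key-value files mirroring the arguments of
#' [sim_config()]. The fragment distribution is stored under a
#' `fragment_distribution` mapping with a `type` key (`mixture` or
#' `empirical`). Unknown keys are rejected rather than silently ignored.
#'
#' @param path Path to a YAML configuration file.
#' @param config A `sim_config` object.
#' @return `read_sim_config()` returns a validated `sim_config`;
#'   `write_sim_config()` returns `path` invisibly.
#' @export
read_sim_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  raw <- yaml::read_yaml(path)
  allowed <- c(config_file_keys(), "fragment_distribution")
  unknown <- setdiff(names(raw), allowed)
  if (length(unknown) > 0) {
    stop("unknown configuration key(s) in ", path, ": ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  fd <- raw$fragment_distribution
  raw$fragment_distribution <- NULL
  args <- raw
  if (!is.null(fd)) {
    if (identical(fd$type, "mixture")) {
      fd$type <- NULL
      args$fragment_distribution <- do.call(fragment_mixture, fd)
    } else if (identical(fd$type, "empirical")) {
      args$fragment_distribution <- fragment_empirical(fd$masses)
    } else {
      stop("fragment_distribution$type must be 'mixture' or 'empirical'",
           call. = FALSE)
    }
  }
  do.call(sim_config, args)
}

#' @rdname read_sim_config
#' @export
write_sim_config <- function(config, path) {
  stopifnot(inherits(config, "sim_config"))
  out <- config[config_file_keys()]
  out <- out[!vapply(out, is.null, logical(1))]
  fd <- unclass(config$fragment_distribution)
  out$fragment_distribution <- fd
  yaml::write_yaml(out, path)
  invisible(path)
}
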