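#' @useDynLib toolscape, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom rlang .data
#' @importFrom generics tidy glance
#' @importFrom ggplot2 autoplot
NULL

# ---- internal plumbing between R objects and the compiled core ------------

cfg_for_cpp <- function(config) {
  cfg <- unclass(config)
  cfg$fragment_distribution <- unclass(cfg$fragment_distribution)
  cfg
}

state_to_world <- function(state, config) {
  na_if_neg <- function(v) { v[v < 0] <- NA_integer_; v }
  trees <- tibble::as_tibble(state$trees)
  trees$alive <- trees$alive == 1L
  trees$death_step <- na_if_neg(trees$death_step)
  trees$parent_tree_id <- na_if_neg(trees$parent_tree_id)
  tools <- tibble::as_tibble(state$tools)
  tools$is_fragment <- tools$is_fragment == 1L
  tools$parent_id <- na_if_neg(tools$parent_id)
  pr <- tibble::as_tibble(state$primates)
  pr <- tibble::tibble(primate_id = seq_len(nrow(pr)) - 1L, x = pr$x, y = pr$y)
  so <- tibble::as_tibble(state$sources)
  so <- tibble::tibble(source_id = seq_len(nrow(so)) - 1L,
                       x = so$x, y = so$y, fragility = so$fragility)
  structure(
    list(config = config, step_index = state$step_index,
         primates = pr, sources = so, trees = trees, tools = tools,
         n_regrow_widened = state$n_regrow_widened),
    class = "toolscape_world")
}

world_to_state <- function(world) {
  neg_if_na <- function(v) { v[is.na(v)] <- -1L; as.integer(v) }
  trees <- world$trees
  tools <- world$tools
  list(
    step_index = as.integer(world$step_index),
    primates = list(x = as.integer(world$primates$x),
                    y = as.integer(world$primates$y)),
    sources = list(x = as.integer(world$sources$x),
                   y = as.integer(world$sources$y),
                   fragility = as.integer(world$sources$fragility)),
    trees = list(x = as.integer(trees$x), y = as.integer(trees$y),
                 age = as.integer(trees$age),
                 alive = as.integer(trees$alive),
                 born_step = as.integer(trees$born_step),
                 death_step = neg_if_na(trees$death_step),
                 parent_tree_id = neg_if_na(trees$parent_tree_id)),
    tools = list(mass = as.numeric(tools$mass),
                 initial_mass = as.numeric(tools$initial_mass),
                 x = as.integer(tools$x), y = as.integer(tools$y),
                 origin_x = as.integer(tools$origin_x),
                 origin_y = as.integer(tools$origin_y),
                 fragility = as.integer(tools$fragility),
                 origin_source_id = as.integer(tools$origin_source_id),
                 parent_id = neg_if_na(tools$parent_id),
                 n_uses = as.integer(tools$n_uses),
                 is_fragment = as.integer(tools$is_fragment),
                 created_step = as.integer(tools$created_step)))
}

ts_tibble <- function(ts) tibble::as_tibble(ts)

bouts_tibble <- function(b) {
  if (is.null(b)) return(NULL)
  b <- tibble::as_tibble(b)
  b$material <- ifelse(b$material_kind == 0L, "source", "tool")
  b$material_kind <- NULL
  b$broke <- b$broke == 1L
  b
}

# ---- world construction and stepping --------------------------------------

#' Initialise a simulation world
#'
#' Places sources, trees and primates on the grid (sources and trees at
#' unique cells; collisions are resampled), assigns each source a fragility
#' drawn uniformly from `fragility_levels`, gives every initial tree an age
#' uniform on `1..tree_lifespan` so the cohort does not die synchronously,
#' and starts with an empty tool registry at step 0. All randomness comes
#' from R's RNG: the same `(config, seed)` always yields the same world.
#'
#' @param config A [sim_config()].
#' @param seed Integer seed; defaults to `config$seed`.
#' @return A `toolscape_world`: a list with `config`, `step_index`, and
#'   tibbles `primates`, `sources`, `trees`, `tools`.
#' @examples
#' w <- initialize_world(sim_config(width = 50, height = 50, n_trees = 20,
#'                                  n_sources = 5, n_primates = 10), seed = 1)
#' nrow(w$trees)
#' @export
initialize_world <- function(config, seed = config$seed) {
  stopifnot(inherits(config, "sim_config"))
  if (is.null(seed)) stop("a seed is required (in the config or as `seed`)",
                          call. = FALSE)
  set.seed(as.integer(seed))
  res <- cpp_sim(cfg_for_cpp(config), NULL, 0L, 1L, FALSE)
  w <- state_to_world(res$state, config)
  w$seed <- as.integer(seed)
  w
}

#' Advance a world by whole time-steps
#'
#' Runs the per-step update `n` times: primates are activated in a freshly
#' shuffled order; each moves one cell in a random Moore direction, and if it
#' lands at or beside a live tree it executes at most one
#' acquisition-transport-use bout; after all primates act, trees age and turn
#' over (when `dynamic_trees` is on). Continues R's RNG stream, so
#' `initialize_world()` followed by `world_step(w, n)` reproduces
#' [simulate_run()] with `n_steps = n` exactly.
#'
#' @param world A `toolscape_world`.
#' @param n Number of steps to advance.
#' @return The advanced world.
#' @export
world_step <- function(world, n = 1) {
  stopifnot(inherits(world, "toolscape_world"), n >= 0)
  if (n == 0) return(world)
  cfg <- world$config
  res <- cpp_sim(cfg_for_cpp(cfg), world_to_state(world), as.integer(n),
                 resolve_record_every(cfg, n), isTRUE(cfg$record_bouts))
  out <- state_to_world(res$state, cfg)
  out$seed <- world$seed
  out
}

#' @export
print.toolscape_world <- function(x, ...) {
  cat("<toolscape_world> step ", x$step_index, ": ",
      nrow(x$primates), " primates, ", sum(x$trees$alive), " live trees, ",
      nrow(x$sources), " sources, ", nrow(x$tools), " tool records\n",
      sep = "")
  invisible(x)
}

# a snapshot is anything carrying sources/trees/tools tibbles + a config
as_snapshot <- function(x) {
  if (inherits(x, c("toolscape_world", "toolscape_run"))) {
    return(list(config = x$config, sources = x$sources, trees = x$trees,
                tools = x$tools))
  }
  stopifnot(is.list(x), all(c("sources", "trees", "tools") %in% names(x)))
  x
}

# ---- individual model rules, exposed for inspection and testing -----------

#' Per-use breakage probability
#'
#' A tool breaks on each use with probability
#' `min(1, baseline_break_prob + fragility / 100)`: a fragility-25 tool with
#' the default 25% baseline breaks half the time, and fragility 75 breaks on
#' every use.
#'
#' @param fragility Fragility score(s) in percentage points (vectorised).
#' @param baseline_break_prob Baseline per-use breakage probability.
#' @return Probabilities clamped to `[0, 1]`.
#' @examples
#' break_probability(c(0, 25, 50, 75))
#' @export
break_probability <- function(fragility, baseline_break_prob = 0.25) {
  pmin(1, pmax(0, baseline_break_prob + fragility / 100))
}

#' Draw fresh hammer masses
#'
#' Fresh tools acquired at a source draw their mass from
#' `Normal(initial_mass_mean, initial_mass_sd)` grams, redrawn (rejection
#' sampling) until at or above `usable_threshold`: a source supplies
#' functional hammers, never instantly exhausted ones.
#'
#' @param n Number of draws.
#' @param config A [sim_config()] supplying the mass parameters.
#' @return Numeric vector of masses in grams, all `>= usable_threshold`.
#' @export
draw_initial_mass <- function(n, config = sim_config()) {
  cpp_draw_initial_mass(as.integer(n), config$initial_mass_mean,
                        config$initial_mass_sd, config$usable_threshold)
}

#' Draw fragment masses
#'
#' @param n Number of draws.
#' @param fragment_distribution A [fragment_mixture()] or
#'   [fragment_empirical()] specification.
#' @return Numeric vector of fragment masses in grams (uncapped; inside a
#'   run a fragment is additionally capped at the breaking tool's mass).
#' @export
draw_fragment_mass <- function(n, fragment_distribution = fragment_mixture()) {
  stopifnot(inherits(fragment_distribution, "fragment_distribution"))
  cpp_draw_fragment_mass(as.integer(n), unclass(fragment_distribution))
}

#' Find the nearest live tree to a position
#'
#' Returns the live tree within `interaction_radius` (default 1: the cell
#' itself or its eight neighbours) of `position`, nearest first, ties broken
#' uniformly at random; dead trees never qualify.
#'
#' @param world A `toolscape_world` (or any snapshot with a `trees` tibble
#'   and `config`).
#' @param position Length-2 integer vector `c(x, y)`.
#' @return One-row tibble describing the tree, or `NULL` if none qualifies.
#' @export
adjacent_live_tree <- function(world, position) {
  s <- as_snapshot(world)
  cfg <- s$config
  id <- cpp_nearest_live_tree(
    as.integer(position[1]), as.integer(position[2]),
    cfg$width, cfg$height, isTRUE(cfg$torus),
    as.integer(s$trees$x), as.integer(s$trees$y),
    as.integer(s$trees$alive), cfg$interaction_radius)
  if (id < 0) return(NULL)
  s$trees[id + 1L, ]
}

#' Find the nearest source or usable tool
#'
#' Scans a Chebyshev radius of `search_radius` (default 2) around `position`
#' for raw-material sources and usable tools (mass at or above
#' `usable_threshold`), pooled: the nearest item wins and equally-near items
#' are chosen uniformly at random. Sub-threshold (exhausted) tools are never
#' candidates.
#'
#' @inheritParams adjacent_live_tree
#' @param position Length-2 integer vector `c(x, y)`.
#' @return One-row tibble with columns `material` (`"source"` or `"tool"`),
#'   `id`, `x`, `y`, `mass` (`NA` for a source) and `distance`, or `NULL` if
#'   nothing usable is in range.
#' @export
find_material <- function(world, position) {
  s <- as_snapshot(world)
  cfg <- s$config
  res <- cpp_find_material(
    as.integer(position[1]), as.integer(position[2]),
    cfg$width, cfg$height, isTRUE(cfg$torus),
    as.integer(s$sources$x), as.integer(s$sources$y),
    as.integer(s$tools$x), as.integer(s$tools$y), as.numeric(s$tools$mass),
    cfg$search_radius, cfg$usable_threshold)
  if (res$kind < 0) return(NULL)
  if (res$kind == 0L) {
    src <- s$sources[res$index + 1L, ]
    out <- tibble::tibble(material = "source", id = src$source_id,
                          x = src$x, y = src$y, mass = NA_real_)
  } else {
    tl <- s$tools[res$index + 1L, ]
    out <- tibble::tibble(material = "tool", id = tl$tool_id,
                          x = tl$x, y = tl$y, mass = tl$mass)
  }
  out$distance <- chebyshev_distance(out$x, out$y, position[1], position[2])
  out
}

#' Apply a breakage event to a tool registry
#'
#' The breakage rule in isolation: the fragment mass is capped at the tool's
#' current mass, subtracted from it (mass is conserved exactly), and the
#' fragment is recorded as an additional tool at the breaking tool's cell,
#' inheriting its fragility and source provenance. Inside a run this happens
#' in the compiled core; this function exposes the same arithmetic on a
#' tools tibble for inspection and testing.
#'
#' @param tools A tools tibble (as in `world$tools`).
#' @param tool_id Id of the breaking tool.
#' @param fragment_mass Drawn fragment mass in grams (pre-cap).
#' @param step Time-step recorded for the fragment.
#' @return The tools tibble with the parent updated and the fragment row
#'   appended.
#' @export
apply_breakage <- function(tools, tool_id, fragment_mass, step = NA_integer_) {
  i <- match(tool_id, tools$tool_id)
  if (is.na(i)) stop("tool_id not found", call. = FALSE)
  m <- min(fragment_mass, tools$mass[i])
  tools$mass[i] <- tools$mass[i] - m
  frag <- tools[i, ]
  frag$tool_id <- max(tools$tool_id) + 1L
  frag$mass <- m
  frag$initial_mass <- m
  frag$parent_id <- tool_id
  frag$n_uses <- 0L
  frag$is_fragment <- TRUE
  frag$created_step <- as.integer(step)
  dplyr::bind_rows(tools, frag)
}
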