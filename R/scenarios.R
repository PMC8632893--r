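#' Deterministic test scenarios
#'
#' Hand-placed worlds with known qualitative outcomes, used to pin down the
#' model's reachability logic independently of its stochastic defaults.
#' Scenario configs may set the break probability to 0 and the initial-mass
#' sd to 0 purely to create deterministic paths; these overrides are
#' test-oriented, not study conditions.
#'
#' `scenario_no_transport()` places every tree strictly more than
#' `location_radius` (3) cells from every source: no acquisition bout can
#' ever initiate, so the tool registry stays empty for any run length and
#' the tool-use-location count is 0 throughout.
#'
#' `scenario_chain()` places one source and a line of trees `spacing` cells
#' apart leading away from it. With spacing at most 4 (a tool discarded in
#' the Moore neighbourhood of one tree can sit within reach, 3 cells, of the
#' next) tools leapfrog tree to tree and some tool's displacement eventually
#' exceeds 3 cells; at spacing 5 or more the chain is broken and no tool can
#' ever pass the first tree's discard neighbourhood.
#'
#' @param width,height Grid size.
#' @param n_primates Primates placed near the chain/grid.
#' @param n_links Number of trees in the chain.
#' @param spacing Chebyshev distance between consecutive chain trees (and
#'   from the source to the first tree, capped at 3 so acquisition works).
#' @param break_prob Baseline break probability override for the scenario.
#' @param seed Seed stored in the config.
#' @return A `sim_config` with preset entity placements.
#' @export
scenario_no_transport <- function(width = 30, height = 30, n_primates = 10,
                                  seed = 1) {
  # sources on the left edge, trees on the right edge, gap >> 3
  sources <- tibble::tibble(x = 0L, y = as.integer(seq(2, height - 3, by = 5)),
                            fragility = 0L)
  trees <- tibble::tibble(x = width - 1L,
                          y = as.integer(seq(1, height - 2, by = 3)))
  primates <- tibble::tibble(
    x = as.integer(rep(seq(5, width - 5, length.out = max(2, n_primates %/% 2)),
                       length.out = n_primates)),
    y = as.integer(rep(c(2L, height - 3L), length.out = n_primates)))
  sim_config(width = width, height = height, n_primates = n_primates,
             n_trees = nrow(trees), n_sources = nrow(sources),
             dynamic_trees = FALSE, n_steps = 1000, seed = seed,
             preset_trees = trees, preset_sources = sources,
             preset_primates = primates)
}

#' @rdname scenario_no_transport
#' @export
scenario_chain <- function(n_links = 5, spacing = 3, width = NULL,
                           n_primates = 20, break_prob = 0, seed = 1) {
  stopifnot(n_links >= 1, spacing >= 1)
  first_hop <- min(spacing, 3L)  # acquisition requires source-tree <= 3
  xs <- as.integer(first_hop + spacing * (seq_len(n_links) - 1L))
  if (is.null(width)) width <- max(xs) + 8L
  height <- 11L
  y0 <- 5L
  sources <- tibble::tibble(x = 0L, y = y0, fragility = 0L)
  trees <- tibble::tibble(x = xs, y = y0)
  primates <- tibble::tibble(
    x = as.integer(rep(c(0L, xs), length.out = n_primates)),
    y = as.integer(rep(c(y0 - 1L, y0 + 1L), length.out = n_primates)))
  sim_config(width = as.integer(width), height = height,
             n_primates = n_primates, n_trees = n_links, n_sources = 1,
             dynamic_trees = FALSE, n_steps = 20000,
             baseline_break_prob = break_prob,
             initial_mass_mean = 5000, initial_mass_sd = 0,
             seed = seed,
             preset_trees = trees, preset_sources = sources,
             preset_primates = primates)
}

#' Brute-force tool-use-location census
#'
#' Independent O(trees x items) re-computation of the tool-use-location
#' count over all tree-source and tree-tool pairs, written in plain
#' vectorised R with no shared code with the simulation core. Intended as an
#' exhaustive oracle on small snapshots; agrees exactly with
#' [count_tool_use_locations()] by construction of the definition.
#'
#' @param x A world, run, or snapshot list.
#' @return Integer count.
#' @export
brute_force_locations <- function(x) {
  s <- as_snapshot(x)
  cfg <- s$config
  live <- s$trees[s$trees$alive, , drop = FALSE]
  if (nrow(live) == 0) return(0L)
  usable <- s$tools[s$tools$mass >= cfg$usable_threshold, , drop = FALSE]
  items_x <- c(s$sources$x, usable$x)
  items_y <- c(s$sources$y, usable$y)
  if (length(items_x) == 0) return(0L)
  n <- 0L
  for (i in seq_len(nrow(live))) {
    d <- chebyshev_distance(live$x[i], live$y[i], items_x, items_y)
    if (any(d <= cfg$location_radius)) n <- n + 1L
  }
  n
}
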