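# fixtures are built in code; nothing on disk

# a compact, active configuration used by invariants tests: dense enough that
# bouts, breakage, reuse and tree turnover all occur within a few hundred steps
active_config <- function(n_steps = 2000, dynamic_trees = TRUE, ...) {
  sim_config(width = 60, height = 60, n_primates = 30, n_trees = 120,
             n_sources = 20, dynamic_trees = dynamic_trees,
             n_steps = n_steps, tree_lifespan = 500, record_bouts = TRUE, ...)
}

# a random small snapshot (trees/sources/tools tables + config) for oracle
# equivalence checks; includes dead trees and sub-threshold tools on purpose
random_snapshot <- function(width = 20, height = 20) {
  n_trees <- sample(1:12, 1)
  n_sources <- sample(0:5, 1)
  n_tools <- sample(0:15, 1)
  cfg <- sim_config(width = width, height = height, n_trees = 1, n_sources = 1,
                    n_primates = 1, seed = 1)
  list(
    config = cfg,
    trees = tibble::tibble(
      tree_id = seq_len(n_trees) - 1L,
      x = sample(0:(width - 1), n_trees, replace = TRUE),
      y = sample(0:(height - 1), n_trees, replace = TRUE),
      alive = sample(c(TRUE, TRUE, TRUE, FALSE), n_trees, replace = TRUE)),
    sources = tibble::tibble(
      source_id = seq_len(n_sources) - 1L,
      x = sample(0:(width - 1), n_sources, replace = TRUE),
      y = sample(0:(height - 1), n_sources, replace = TRUE),
      fragility = sample(c(0L, 25L, 50L, 75L), n_sources, replace = TRUE)),
    tools = tibble::tibble(
      tool_id = seq_len(n_tools) - 1L,
      x = sample(0:(width - 1), n_tools, replace = TRUE),
      y = sample(0:(height - 1), n_tools, replace = TRUE),
      mass = stats::runif(n_tools, 0, 6000)))
}

# brute-force material search: every source and usable tool within the search
# radius, pooled; returns the set of nearest candidates (or empty tibble)
brute_force_material_candidates <- function(snapshot, position) {
  cfg <- snapshot$config
  usable <- snapshot$tools[snapshot$tools$mass >= cfg$usable_threshold, ,
                           drop = FALSE]
  items <- rbind(
    data.frame(material = rep("source", nrow(snapshot$sources)),
               id = snapshot$sources$source_id,
               x = snapshot$sources$x, y = snapshot$sources$y),
    data.frame(material = rep("tool", nrow(usable)),
               id = usable$tool_id, x = usable$x, y = usable$y))
  if (nrow(items) == 0) return(items)
  d <- chebyshev_distance(items$x, items$y, position[1], position[2])
  items <- items[d <= cfg$search_radius, , drop = FALSE]
  d <- d[d <= cfg$search_radius]
  if (nrow(items) == 0) return(items)
  items[d == min(d), , drop = FALSE]
}

# mass-conservation audit: for every tool, initial mass must equal current
# mass plus the initial masses of its direct fragments
audit_mass_conservation <- function(tools) {
  shed <- tapply(tools$initial_mass, factor(tools$parent_id,
                                            levels = tools$tool_id),
                 sum, default = 0)
  max(abs(tools$initial_mass - tools$mass - as.numeric(shed)))
}
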