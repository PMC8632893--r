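test_that("world initialisation places entities uniquely and reproducibly", {
  cfg <- sim_config(width = 40, height = 40, n_primates = 15, n_trees = 30,
                    n_sources = 8, tree_lifespan = 100)
  w <- initialize_world(cfg, seed = 11)
  expect_equal(nrow(w$trees), 30)
  expect_equal(nrow(w$sources), 8)
  expect_equal(nrow(w$primates), 15)
  expect_equal(nrow(w$tools), 0)
  expect_equal(w$step_index, 0)
  # trees and sources on unique cells
  occ <- c(paste(w$trees$x, w$trees$y), paste(w$sources$x, w$sources$y))
  expect_equal(anyDuplicated(occ), 0L)
  # attributes drawn from the configured sets
  expect_true(all(w$sources$fragility %in% c(0, 25, 50, 75)))
  expect_true(all(w$trees$age >= 1 & w$trees$age <= 100))
  expect_true(all(w$trees$alive))
  # everything in-grid
  expect_true(all(w$primates$x >= 0 & w$primates$x < 40 &
                    w$primates$y >= 0 & w$primates$y < 40))
  # determinism under a fixed seed
  w2 <- initialize_world(cfg, seed = 11)
  expect_identical(w$trees, w2$trees)
  expect_identical(w$sources, w2$sources)
  expect_identical(w$primates, w2$primates)
})

test_that("extreme factorial corners initialise at full entity counts", {
  w <- initialize_world(sim_config(n_trees = 2000, n_sources = 500), seed = 3)
  expect_equal(sum(w$trees$alive), 2000)
  expect_equal(nrow(w$sources), 500)
  w <- initialize_world(sim_config(width = 5, height = 5, n_trees = 1,
                                   n_sources = 1, n_primates = 1), seed = 3)
  expect_false(w$trees$x == w$sources$x && w$trees$y == w$sources$y)
})

test_that("movement is one Moore step, uniform over in-grid neighbours", {
  set.seed(42)
  mv <- toolscape:::cpp_random_moves(12000, 10, 10, 250, 250, FALSE)
  d <- chebyshev_distance(mv[, 1], mv[, 2], 10, 10)
  expect_true(all(d == 1))  # always moves, never further than 1 cell
  dirs <- paste(mv[, 1] - 10, mv[, 2] - 10)
  expect_equal(length(unique(dirs)), 8)
  p <- stats::chisq.test(table(dirs))$p.value
  expect_gt(p, 1e-4)

  # at a corner only the 3 in-grid neighbours are available
  set.seed(42)
  mv <- toolscape:::cpp_random_moves(6000, 0, 0, 250, 250, FALSE)
  expect_true(all(mv >= 0))
  dirs <- paste(mv[, 1], mv[, 2])
  expect_setequal(unique(dirs), c("0 1", "1 0", "1 1"))
  expect_gt(stats::chisq.test(table(dirs))$p.value, 1e-4)
})

test_that("tree adjacency returns the nearest live tree only", {
  snap <- list(
    config = sim_config(width = 20, height = 20, n_trees = 1, n_sources = 1,
                        n_primates = 1),
    trees = tibble::tibble(tree_id = 0:1, x = c(5L, 9L), y = c(5L, 5L),
                           alive = c(TRUE, TRUE)),
    sources = tibble::tibble(source_id = integer(), x = integer(),
                             y = integer(), fragility = integer()),
    tools = tibble::tibble(tool_id = integer(), x = integer(), y = integer(),
                           mass = numeric()))
  expect_equal(adjacent_live_tree(snap, c(5, 6))$tree_id, 0)
  expect_null(adjacent_live_tree(snap, c(5, 7)))   # distance 2: out of reach
  # a dead tree underfoot never beats a live tree one cell away
  snap$trees <- tibble::tibble(tree_id = 0:1, x = c(5L, 5L), y = c(6L, 5L),
                               alive = c(FALSE, TRUE))
  expect_equal(adjacent_live_tree(snap, c(5, 6))$tree_id, 1)
  # equidistant live trees: both chosen, roughly equally often
  snap$trees <- tibble::tibble(tree_id = 0:1, x = c(4L, 6L), y = c(5L, 5L),
                               alive = c(TRUE, TRUE))
  set.seed(9)
  picks <- replicate(4000, adjacent_live_tree(snap, c(5, 5))$tree_id)
  expect_gt(mean(picks == 0), 0.45)
  expect_lt(mean(picks == 0), 0.55)
})

test_that("material search pools sources and usable tools, nearest first", {
  snap <- list(
    config = sim_config(width = 20, height = 20, n_trees = 1, n_sources = 1,
                        n_primates = 1),
    trees = tibble::tibble(tree_id = integer(), x = integer(), y = integer(),
                           alive = logical()),
    sources = tibble::tibble(source_id = 0L, x = 12L, y = 10L,
                             fragility = 25L),
    tools = tibble::tibble(tool_id = 0L, x = 11L, y = 10L, mass = 2500))
  # usable tool at distance 1 beats source at distance 2
  got <- find_material(snap, c(10, 10))
  expect_equal(got$material, "tool")
  expect_equal(got$distance, 1)
  # a 1999 g tool is exhausted: never selected even when it is the only item
  snap$tools$mass <- 1999
  snap$sources <- snap$sources[0, ]
  expect_null(find_material(snap, c(10, 10)))
  # beyond the search radius nothing is found
  snap$tools$mass <- 5000
  expect_null(find_material(snap, c(15, 10)))
})

test_that("equidistant source and tool are chosen 50/50", {
  snap <- list(
    config = sim_config(width = 20, height = 20, n_trees = 1, n_sources = 1,
                        n_primates = 1),
    trees = tibble::tibble(tree_id = integer(), x = integer(), y = integer(),
                           alive = logical()),
    sources = tibble::tibble(source_id = 0L, x = 8L, y = 10L, fragility = 0L),
    tools = tibble::tibble(tool_id = 0L, x = 12L, y = 10L, mass = 3000))
  set.seed(31)
  picks <- replicate(4000, find_material(snap, c(10, 10))$material)
  expect_gt(mean(picks == "source"), 0.45)
  expect_lt(mean(picks == "source"), 0.55)
})

test_that("break probability is baseline plus fragility, clamped to one", {
  expect_equal(break_probability(25), 0.50)
  expect_equal(break_probability(0), 0.25)
  expect_equal(break_probability(75), 1.00)
  expect_equal(break_probability(c(0, 25, 50, 75), baseline_break_prob = 0.1),
               c(0.10, 0.35, 0.60, 0.85))
})

test_that("initial masses follow the truncated normal of fresh hammers", {
  cfg0 <- sim_config(initial_mass_mean = 4000, initial_mass_sd = 0)
  expect_equal(draw_initial_mass(5, cfg0), rep(4000, 5))

  cfg <- sim_config(initial_mass_mean = 4000, initial_mass_sd = 1000)
  set.seed(5)
  m <- draw_initial_mass(10000, cfg)
  expect_true(all(m >= 2000))
  # truncated-normal moments as the independent oracle
  a <- (2000 - 4000) / 1000
  lambda <- stats::dnorm(a) / (1 - stats::pnorm(a))
  mean_trunc <- 4000 + 1000 * lambda
  sd_trunc <- 1000 * sqrt(1 + a * lambda - lambda^2)
  expect_lt(abs(mean(m) - mean_trunc), 3 * sd_trunc / sqrt(10000))
})

test_that("breakage conserves mass, caps fragments, and inherits provenance", {
  tools <- tibble::tibble(
    tool_id = 0L, x = 3L, y = 4L, origin_x = 0L, origin_y = 0L,
    mass = 5000, initial_mass = 5000, fragility = 50L,
    origin_source_id = 2L, parent_id = NA_integer_, n_uses = 7L,
    is_fragment = FALSE, created_step = 1L)
  out <- apply_breakage(tools, 0L, 300, step = 9L)
  expect_equal(nrow(out), 2)
  expect_equal(out$mass, c(4700, 300))
  expect_equal(out$initial_mass[2], 300)
  expect_true(out$is_fragment[2])
  expect_equal(out$x[2], 3L)
  expect_equal(out$fragility[2], 50L)
  expect_equal(out$origin_source_id[2], 2L)
  expect_equal(out$parent_id[2], 0L)
  expect_equal(sum(out$mass), 5000)  # conservation
  # an oversized draw is capped at the tool's whole mass
  out2 <- apply_breakage(tools, 0L, 99999)
  expect_equal(out2$mass, c(0, 5000))
  expect_error(apply_breakage(tools, 42L, 10), "not found")
})

test_that("fragment mixture is right-skewed with rare large fragments", {
  set.seed(8)
  f <- draw_fragment_mass(20000, fragment_mixture())
  expect_true(all(f > 0))
  expect_gt(mean(f), stats::median(f))   # right skew
  # component means: 90% small (~9 g), 10% large (~84 g)
  expect_lt(stats::median(f), 20)
  expect_gt(stats::quantile(f, 0.97), 50)
})
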