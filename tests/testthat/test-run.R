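test_that("a run is fully determined by its configuration and seed", {
  cfg <- active_config(n_steps = 400)
  r1 <- simulate_run(cfg, seed = 7)
  r2 <- simulate_run(cfg, seed = 7)
  expect_equal(r1$tools, r2$tools)
  expect_equal(r1$trees, r2$trees)
  expect_equal(r1$timeseries, r2$timeseries)
  expect_equal(r1$bouts, r2$bouts)
  r3 <- simulate_run(cfg, seed = 8)
  expect_false(identical(r1$tools, r3$tools))
})

test_that("stepping a world reproduces the one-shot run exactly", {
  cfg <- active_config(n_steps = 300)
  run <- simulate_run(cfg, seed = 13)
  w <- initialize_world(cfg, seed = 13)
  w <- world_step(w, 120)
  w <- world_step(w, 180)
  expect_equal(w$step_index, 300)
  expect_equal(w$tools, run$tools)
  expect_equal(w$trees, run$trees)
  expect_equal(w$primates, run$primates)
})

test_that("a longer run extends a shorter one without rewriting its past", {
  cfg <- active_config(n_steps = 150)
  short <- simulate_run(cfg, seed = 21)
  long <- simulate_run(cfg, seed = 21, n_steps = 350)
  n <- nrow(short$timeseries)
  expect_equal(long$timeseries[seq_len(n), ], short$timeseries)
})

test_that("a zero-step run records only the initial census", {
  cfg <- active_config(n_steps = 0)
  run <- simulate_run(cfg, seed = 2)
  expect_equal(nrow(run$timeseries), 1)
  expect_equal(run$timeseries$step, 0)
  expect_equal(nrow(run$tools), 0)
  expect_equal(run$timeseries$n_locations, count_tool_use_locations(run))
})

test_that("core invariants hold along an active seeded run", {
  cfg <- active_config(n_steps = 2000)
  run <- simulate_run(cfg, seed = 5)
  tl <- run$tools
  b <- run$bouts
  expect_gt(nrow(tl), 50)       # the scenario is genuinely active
  expect_gt(sum(b$broke), 20)
  expect_gt(sum(b$material == "tool"), 20)   # reuse happens

  # live-tree count is constant at every recorded boundary
  expect_true(all(run$timeseries$n_live_trees == cfg$n_trees))

  # per-bout geometry: material within 3 cells of the tree, and the whole
  # bout displaces the material at most search + interaction + 1 = 4 cells
  expect_true(all(b$material_tree_distance <= 3))
  hop <- chebyshev_distance(b$material_x, b$material_y, b$x, b$y)
  expect_true(all(hop <= 4))

  # discard cell is the tree's cell or a Moore neighbour
  expect_true(all(chebyshev_distance(b$x, b$y, b$tree_x, b$tree_y) <= 1))

  # no exhausted tool is ever selected for reuse
  expect_true(all(b$material_mass[b$material == "tool"] >=
                    cfg$usable_threshold))

  # every tool use is logged: use counts sum to the bout count
  expect_equal(sum(tl$n_uses), nrow(b))

  # mass conservation per lineage, exact to rounding
  expect_lt(audit_mass_conservation(tl), 1e-9)
  expect_true(all(tl$mass >= 0))
  expect_true(all(tl$mass <= tl$initial_mass + 1e-12))

  # provenance: tools inherit the fragility of their origin source,
  # fragments inherit origin and fragility from their parent
  expect_equal(tl$fragility,
               run$sources$fragility[tl$origin_source_id + 1L])
  fr <- tl[tl$is_fragment, ]
  par <- match(fr$parent_id, tl$tool_id)
  expect_equal(fr$origin_source_id, tl$origin_source_id[par])
  expect_equal(fr$created_step >= tl$created_step[par], rep(TRUE, nrow(fr)))

  # all positions inside the grid
  expect_true(all(tl$x >= 0 & tl$x < cfg$width &
                    tl$y >= 0 & tl$y < cfg$height))
})

test_that("static tree layers are frozen; dynamic layers turn over in place", {
  cfg <- active_config(n_steps = 1200, dynamic_trees = FALSE)
  w0 <- initialize_world(cfg, seed = 4)
  run <- simulate_run(cfg, seed = 4)
  expect_equal(run$trees, w0$trees)   # no aging, no death, no movement

  cfgd <- active_config(n_steps = 1200, dynamic_trees = TRUE)
  rund <- simulate_run(cfgd, seed = 4)
  trees <- rund$trees
  expect_gt(nrow(trees), cfgd$n_trees)              # regrowth happened
  expect_equal(sum(trees$alive), cfgd$n_trees)      # but the count held
  dead <- trees[!trees$alive, ]
  expect_true(all(!is.na(dead$death_step)))
  # regrown trees appear within the regrow radius of their parent and die
  # exactly one lifespan after birth
  regrown <- trees[!is.na(trees$parent_tree_id), ]
  par <- match(regrown$parent_tree_id, trees$tree_id)
  expect_true(all(chebyshev_distance(regrown$x, regrown$y,
                                     trees$x[par], trees$y[par])
                  <= cfgd$regrow_radius))
  closed <- regrown[!is.na(regrown$death_step), ]
  expect_true(all(closed$death_step - closed$born_step == cfgd$tree_lifespan))
})

test_that("runs persist to plain text and reload exactly", {
  dir <- withr::local_tempdir()
  cfg <- active_config(n_steps = 300)
  run <- simulate_run(cfg, seed = 17)
  write_run(run, dir)
  expect_true(all(file.exists(file.path(
    dir, c("metadata.json", "timeseries.csv", "tools.csv", "sources.csv",
           "trees.csv", "primates.csv", "bouts.csv")))))
  back <- read_run(dir)
  expect_equal(back$tools, run$tools)
  expect_equal(back$trees, run$trees)
  expect_equal(back$timeseries, run$timeseries)
  expect_equal(back$bouts, run$bouts)
  expect_equal(back$seed, run$seed)
  expect_equal(back$config, run$config)

  # column schemas are frozen
  expect_named(run$tools,
               c("tool_id", "x", "y", "origin_x", "origin_y", "mass",
                 "initial_mass", "fragility", "origin_source_id", "parent_id",
                 "n_uses", "is_fragment", "created_step"))
  expect_named(run$timeseries,
               c("step", "n_locations", "n_live_trees", "max_displacement"))

  # a directory without metadata is refused loudly
  file.remove(file.path(dir, "metadata.json"))
  expect_error(read_run(dir), "metadata.json")
})
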