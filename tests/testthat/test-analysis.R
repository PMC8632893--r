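fake_run <- function(tools, sources, trees = NULL, width = 30, height = 30) {
  cfg <- sim_config(width = width, height = height, n_trees = 1,
                    n_sources = 1, n_primates = 1)
  if (is.null(trees)) {
    trees <- tibble::tibble(tree_id = integer(), x = integer(),
                            y = integer(), alive = logical())
  }
  structure(list(config = cfg, sources = sources, trees = trees,
                 tools = tools),
            class = "toolscape_world")
}

tool_row <- function(tool_id, x, y, mass, is_fragment = FALSE,
                     origin_x = 0L, origin_y = 0L) {
  tibble::tibble(tool_id = tool_id, x = as.integer(x), y = as.integer(y),
                 origin_x = as.integer(origin_x),
                 origin_y = as.integer(origin_y),
                 mass = mass, initial_mass = mass + 1,
                 fragility = 0L, origin_source_id = 0L,
                 parent_id = NA_integer_, n_uses = 1L,
                 is_fragment = is_fragment, created_step = 1L)
}

one_source <- tibble::tibble(source_id = 0L, x = 0L, y = 0L, fragility = 0L)

test_that("assemblages partition the record and tally usable fragments as usable", {
  tools <- dplyr::bind_rows(
    tool_row(0L, 5, 5, 4000),                       # usable tool
    tool_row(1L, 5, 5, 150, is_fragment = TRUE),    # its small fragment
    tool_row(2L, 9, 9, 1200),                       # exhausted tool
    tool_row(3L, 9, 9, 2600, is_fragment = TRUE))   # usable fragment
  run <- fake_run(tools, one_source)
  a <- build_assemblages(run)
  expect_equal(nrow(a), 2)
  r1 <- a[a$x == 5, ]
  expect_equal(r1$n_total, 2)
  expect_equal(r1$n_usable, 1)
  expect_equal(r1$n_fragments, 1)
  r2 <- a[a$x == 9, ]
  expect_equal(r2$n_usable, 1)      # the heavy fragment counts as usable
  expect_equal(r2$n_exhausted, 1)
  expect_equal(r2$n_fragments, 0)
  # partition + conservation
  expect_equal(a$n_total, a$n_usable + a$n_exhausted + a$n_fragments)
  expect_equal(sum(a$n_total), nrow(tools))
  expect_equal(r1$nearest_source_distance, 5)
  expect_equal(r1$total_mass, 4150)
})

test_that("the usable-assemblage percentage behaves like a proportion", {
  tools <- tool_row(0L, 3, 3, 5000)
  expect_equal(pct_assemblages_with_usable(
    build_assemblages(fake_run(tools, one_source))), 100)
  # 40 cells, exactly one holding a usable tool: 2.5%
  tools <- dplyr::bind_rows(lapply(1:40, function(i) {
    tool_row(i, i %% 7, i %/% 7, if (i == 1) 3000 else 100,
             is_fragment = (i != 1))
  }))
  tools$x <- as.integer(seq_len(40) - 1L) %% 20L
  tools$y <- as.integer(seq_len(40) - 1L) %/% 20L
  a <- build_assemblages(fake_run(tools, one_source))
  expect_equal(nrow(a), 40)
  expect_equal(pct_assemblages_with_usable(a), 2.5)
  # adding a fragment-only cell can only dilute the percentage
  more <- dplyr::bind_rows(tools, tool_row(99L, 25, 25, 80,
                                           is_fragment = TRUE))
  expect_lt(pct_assemblages_with_usable(
    build_assemblages(fake_run(more, one_source))),
    pct_assemblages_with_usable(a))
  expect_error(pct_assemblages_with_usable(
    build_assemblages(fake_run(tools[0, ], one_source))), "empty")
})

test_that("max displacement tracks non-fragment tools from their origin", {
  expect_equal(max_displacement(fake_run(tool_row(0L, 3, 3, 100)[0, ],
                                         one_source)), 0)
  tools <- dplyr::bind_rows(
    tool_row(0L, 4, 2, 3000, origin_x = 0, origin_y = 0),
    tool_row(1L, 9, 9, 90, is_fragment = TRUE, origin_x = 0, origin_y = 0))
  expect_equal(max_displacement(fake_run(tools, one_source)), 4)
})

test_that("synthetic exponential counts recover their decay slope", {
  # counts proportional to exp(-d): fitted log-linear slope near -1
  d <- rep(0:5, each = 8)
  a <- tibble::tibble(x = seq_along(d), y = 1L,
                      n_usable = 1L, n_exhausted = 0L, n_fragments = 0L,
                      n_total = round(1000 * exp(-d)), total_mass = 1,
                      nearest_source_distance = d)
  run <- fake_run(tool_row(0L, 1, 1, 3000), one_source)
  dec <- distance_decay(run, assemblages = a)
  expect_false(dec$counts$degenerate)
  expect_lt(abs(dec$counts$slope - (-1)), 0.1)
  expect_lt(dec$counts$spearman_rho, -0.9)

  # constant counts: slope indistinguishable from zero
  a$n_total <- 50L
  dec0 <- suppressWarnings(distance_decay(run, assemblages = a))  # perfect fit
  expect_lt(abs(dec0$counts$slope), 0.05)

  # a single distance is degenerate and flagged, never silently fitted
  a$nearest_source_distance <- 2
  decd <- distance_decay(run, assemblages = a)
  expect_true(decd$counts$degenerate)
  expect_true(is.na(decd$counts$slope))

  # tidy() reports one row per relation
  td <- generics::tidy(dec)
  expect_equal(td$relation, c("counts", "mass"))
})

test_that("tool mass decays with distance from its own origin source", {
  # construct usable tools whose mass halves every 2 cells of displacement
  d <- rep(0:4, each = 5)
  tools <- dplyr::bind_rows(lapply(seq_along(d), function(i) {
    tool_row(i, d[i], 0, 8000 * 2^(-d[i] / 2), origin_x = 0, origin_y = 0)
  }))
  run <- fake_run(tools, one_source)
  dec <- suppressWarnings(distance_decay(run))  # exact log-line
  expect_false(dec$mass$degenerate)
  expect_lt(abs(dec$mass$slope - (-log(2) / 2)), 0.02)
  expect_lt(dec$mass$spearman_rho, -0.95)
})

test_that("sweep statistics separate group effects and report pooled fractions", {
  base <- tibble::tibble(
    n_trees = rep(c(100L, 500L, 1000L, 2000L), each = 6),
    n_sources = rep(rep(c(10L, 100L, 500L), each = 2), 4),
    dynamic_trees = rep(c(FALSE, TRUE), 12))
  # identical displacement everywhere: the rank test degenerates (all ties)
  s0 <- base
  s0$max_displacement <- 5
  s0$any_transport_beyond_3 <- TRUE
  s0$n_locations_start <- 1L
  s0$n_locations_end <- 2L
  st0 <- suppressWarnings(sweep_statistics(s0))  # constant response
  expect_true(is.nan(unname(st0$kw_trees$statistic)))
  expect_equal(st0$frac_transport_beyond_3, 1)
  expect_equal(st0$frac_locations_increase, 1)

  # an exactly linear response is fitted with R^2 = 1
  s1 <- s0
  s1$max_displacement <- 0.01 * s1$n_trees + 0.002 * s1$n_sources
  st1 <- suppressWarnings(sweep_statistics(s1))  # exact linear response
  expect_equal(st1$ols_r_squared, 1)
  expect_gt(st1$std_coef_trees, st1$std_coef_sources)

  # a single group cannot be tested and says so
  s2 <- s1
  s2$n_trees <- 100L
  expect_message(suppressWarnings(sweep_statistics(s2)), "fewer than 2 groups")

  g <- generics::glance(st1)
  expect_equal(g$n_runs, 24)
  expect_equal(g$frac_locations_increase, 1)
})
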