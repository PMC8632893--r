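#' Count tool-use locations
#'
#' A tool-use location is a live tree within `location_radius` (default 3)
#' Chebyshev cells of a raw-material source or of a usable pounding tool
#' (mass at or above `usable_threshold`). At step 0, before any tool exists,
#' this reduces to tree-source proximity; as transport redistributes usable
#' tools, trees far from any source can become tool-use locations — the
#' niche-construction signal the model tracks.
#'
#' @param x A `toolscape_world`, `toolscape_run`, or snapshot list with
#'   `trees`, `sources`, `tools` tibbles and a `config`.
#' @return Integer count of live trees where tool use is possible.
#' @examples
#' w <- initialize_world(sim_config(width = 40, height = 40, n_trees = 15,
#'                                  n_sources = 4, n_primates = 5), seed = 1)
#' count_tool_use_locations(w)
#' @export
count_tool_use_locations <- function(x) {
  s <- as_snapshot(x)
  cfg <- s$config
  live <- s$trees[s$trees$alive, ]
  cpp_count_locations(
    cfg$width, cfg$height, isTRUE(cfg$torus),
    as.integer(live$x), as.integer(live$y),
    as.integer(s$sources$x), as.integer(s$sources$y),
    as.integer(s$tools$x), as.integer(s$tools$y), as.numeric(s$tools$mass),
    cfg$location_radius, cfg$usable_threshold)
}

#' Maximum tool displacement from origin
#'
#' The largest Chebyshev distance between any non-fragment tool's origin
#' source and its final position — the run-level measure of how far
#' accumulated short transport bouts have carried stone. Fragments are
#' excluded: they are never transported and record the breakage site, not a
#' transport trajectory.
#'
#' @param run A `toolscape_run` (or world).
#' @return Distance in cells; 0 if no tools were ever created.
#' @export
max_displacement <- function(run) {
  tl <- as_snapshot(run)$tools
  tl <- tl[!tl$is_fragment, ]
  if (nrow(tl) == 0) return(0)
  max(chebyshev_distance(tl$origin_x, tl$origin_y, tl$x, tl$y))
}

#' Build the per-cell assemblage table
#'
#' Groups every tool record by its final grid cell — the archaeological view
#' of the run. Each assemblage row reports its composition (usable tools,
#' exhausted tools, fragments), total stone mass, and the Chebyshev distance
#' to the nearest source. A fragment heavy enough to be re-used counts as
#' usable (it behaves as a tool in the model), so the three classes
#' partition the records: `n_total = n_usable + n_exhausted + n_fragments`.
#'
#' @param run A `toolscape_run` (or world/snapshot).
#' @return A tibble with one row per occupied cell: `x`, `y`, `n_usable`,
#'   `n_exhausted`, `n_fragments`, `n_total`, `total_mass`,
#'   `nearest_source_distance`.
#' @export
build_assemblages <- function(run) {
  s <- as_snapshot(run)
  thr <- s$config$usable_threshold
  tl <- s$tools
  tab <- tl |>
    dplyr::mutate(
      class = dplyr::case_when(
        .data$mass >= thr ~ "usable",
        !.data$is_fragment ~ "exhausted",
        TRUE ~ "fragment")) |>
    dplyr::group_by(.data$x, .data$y) |>
    dplyr::summarise(
      n_usable = sum(.data$class == "usable"),
      n_exhausted = sum(.data$class == "exhausted"),
      n_fragments = sum(.data$class == "fragment"),
      n_total = dplyr::n(),
      total_mass = sum(.data$mass),
      .groups = "drop") |>
    dplyr::arrange(.data$x, .data$y)
  tab$nearest_source_distance <-
    nearest_source_distance(tab$x, tab$y, s$sources)
  tab
}

#' Percentage of assemblages containing a usable tool
#'
#' The share of occupied grid cells whose accumulated record still holds at
#' least one usable pounding tool. Under conditions of extensive transport
#' this can drop to a few percent: usable tools keep moving on while
#' fragments stay put, so the behaviour's most recognisable material
#' signature becomes rare in its own record.
#'
#' @param assemblages An assemblage table from [build_assemblages()].
#' @return Percentage in `[0, 100]`.
#' @export
pct_assemblages_with_usable <- function(assemblages) {
  if (nrow(assemblages) == 0) {
    stop("assemblage table is empty: no tool records, percentage undefined",
         call. = FALSE)
  }
  100 * mean(assemblages$n_usable >= 1)
}

#' Distance-decay structure of the material record
#'
#' Quantifies the two decay relationships that characterise the record:
#' (a) assemblage size vs distance — per-cell total record count against the
#' distance to the nearest source, and (b) tool mass vs transport distance —
#' each usable tool's mass against the distance from its *own* origin source
#' (provenance distance, not nearest-source distance). For each relation a
#' Spearman rank correlation (the robust statistic) and an exponential-decay
#' fit by least squares on the log scale are reported; counts use a `+1`
#' offset to protect zeros, masses are strictly positive and fitted directly.
#'
#' @param run A `toolscape_run`.
#' @param assemblages Optional precomputed [build_assemblages()] table.
#' @return A `toolscape_decay` object; see [tidy.toolscape_decay()].
#' @export
distance_decay <- function(run, assemblages = build_assemblages(run)) {
  s <- as_snapshot(run)
  thr <- s$config$usable_threshold

  fit_one <- function(d, y, offset) {
    out <- list(n = length(d), degenerate = FALSE,
                spearman_rho = NA_real_, spearman_p = NA_real_,
                slope = NA_real_, intercept = NA_real_,
                r_squared = NA_real_)
    if (length(d) < 3 || length(unique(d)) < 2) {
      out$degenerate <- TRUE
      return(out)
    }
    ct <- suppressWarnings(stats::cor.test(d, y, method = "spearman"))
    out$spearman_rho <- unname(ct$estimate)
    out$spearman_p <- ct$p.value
    fit <- stats::lm(log(y + offset) ~ d)
    out$slope <- unname(stats::coef(fit)[2])
    out$intercept <- unname(stats::coef(fit)[1])
    out$r_squared <- summary(fit)$r.squared
    out
  }

  counts <- fit_one(assemblages$nearest_source_distance, assemblages$n_total,
                    offset = 1)

  usable <- s$tools[s$tools$mass >= thr, ]
  mass <- fit_one(
    chebyshev_distance(usable$origin_x, usable$origin_y, usable$x, usable$y),
    usable$mass, offset = 0)

  structure(list(counts = counts, mass = mass,
                 data = list(assemblages = assemblages, usable = usable)),
            class = "toolscape_decay")
}

#' @export
print.toolscape_decay <- function(x, ...) {
  fmt <- function(f, what) {
    if (f$degenerate) {
      cat("  ", what, ": degenerate (fewer than 2 distinct distances)\n",
          sep = "")
    } else {
      cat(sprintf("  %s: spearman rho %.3f (p %.3g), log-linear slope %.4f\n",
                  what, f$spearman_rho, f$spearman_p, f$slope))
    }
  }
  cat("<toolscape_decay>\n")
  fmt(x$counts, "assemblage counts vs nearest-source distance")
  fmt(x$mass, "usable tool mass vs own-source distance")
  invisible(x)
}

#' Tidy distance-decay fits
#'
#' `tidy()` gives one row per relation (`counts`, `mass`) with the rank
#' correlation and exponential-fit terms; `glance()` a one-row overview.
#'
#' @param x A `toolscape_decay`.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.toolscape_decay <- function(x, ...) {
  row <- function(nm, f) {
    tibble::tibble(relation = nm, n = f$n, degenerate = f$degenerate,
                   spearman_rho = f$spearman_rho, spearman_p = f$spearman_p,
                   slope = f$slope, intercept = f$intercept,
                   r_squared = f$r_squared)
  }
  dplyr::bind_rows(row("counts", x$counts), row("mass", x$mass))
}

#' @rdname tidy.toolscape_decay
#' @export
glance.toolscape_decay <- function(x, ...) {
  tibble::tibble(counts_slope = x$counts$slope,
                 counts_spearman_rho = x$counts$spearman_rho,
                 mass_slope = x$mass$slope,
                 mass_spearman_rho = x$mass$spearman_rho,
                 degenerate = x$counts$degenerate || x$mass$degenerate)
}

#' Sweep-level statistics
#'
#' The cross-run sensitivity analysis over a factorial sweep table: a
#' Kruskal-Wallis test of maximum displacement across tree-count groups (and
#' across source-count groups), an OLS regression of maximum displacement on
#' tree and source counts with R-squared and standardised coefficients, and
#' the pooled fractions of runs showing transport beyond the
#' tool-use-location radius and net growth in tool-use locations.
#'
#' @param summaries A tibble of per-run rows from [run_sweep()] or
#'   [summarize_run()], with columns `max_displacement`, `n_trees`,
#'   `n_sources`, `any_transport_beyond_3`, `n_locations_start`,
#'   `n_locations_end`.
#' @return A `toolscape_sweep_stats` object; `tidy()`/`glance()` methods
#'   give tabular views.
#' @export
sweep_statistics <- function(summaries) {
  stopifnot(nrow(summaries) >= 2)
  kw <- function(values, groups) {
    if (length(unique(groups)) < 2) {
      message("Kruskal-Wallis skipped: fewer than 2 groups")
      return(NULL)
    }
    stats::kruskal.test(values, factor(groups))
  }
  kw_trees <- kw(summaries$max_displacement, summaries$n_trees)
  kw_sources <- kw(summaries$max_displacement, summaries$n_sources)

  ols <- NULL
  if (length(unique(summaries$n_trees)) > 1 &&
      length(unique(summaries$n_sources)) > 1) {
    ols <- stats::lm(max_displacement ~ n_trees + n_sources, data = summaries)
  }
  std_coef <- function(fit, var) {
    unname(stats::coef(fit)[var]) * stats::sd(summaries[[var]]) /
      stats::sd(summaries$max_displacement)
  }
  structure(
    list(
      kw_trees = kw_trees, kw_sources = kw_sources, ols = ols,
      ols_r_squared = if (!is.null(ols)) summary(ols)$r.squared else NA_real_,
      std_coef_trees = if (!is.null(ols)) std_coef(ols, "n_trees") else NA_real_,
      std_coef_sources = if (!is.null(ols)) std_coef(ols, "n_sources") else NA_real_,
      frac_transport_beyond_3 = mean(summaries$any_transport_beyond_3),
      frac_locations_increase =
        mean(summaries$n_locations_end > summaries$n_locations_start),
      n_runs = nrow(summaries)),
    class = "toolscape_sweep_stats")
}

#' @export
print.toolscape_sweep_stats <- function(x, ...) {
  cat("<toolscape_sweep_stats> over", x$n_runs, "runs\n")
  if (!is.null(x$kw_trees))
    cat(sprintf("  KW displacement ~ trees: chi-sq %.1f (p %.3g)\n",
                x$kw_trees$statistic, x$kw_trees$p.value))
  if (!is.null(x$kw_sources))
    cat(sprintf("  KW displacement ~ sources: chi-sq %.1f (p %.3g)\n",
                x$kw_sources$statistic, x$kw_sources$p.value))
  if (!is.null(x$ols))
    cat(sprintf("  OLS displacement ~ trees + sources: R^2 %.3f (std coefs %.3f, %.3f)\n",
                x$ols_r_squared, x$std_coef_trees, x$std_coef_sources))
  cat(sprintf("  runs with transport beyond 3 cells: %.1f%%\n",
              100 * x$frac_transport_beyond_3))
  cat(sprintf("  runs ending with more tool-use locations: %.1f%%\n",
              100 * x$frac_locations_increase))
  invisible(x)
}

#' Tidy sweep statistics
#'
#' `tidy()` returns one row per reported statistic; `glance()` a one-row
#' summary with the headline fractions, KW statistics and OLS fit.
#'
#' @param x A `toolscape_sweep_stats`.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.toolscape_sweep_stats <- function(x, ...) {
  rows <- list()
  if (!is.null(x$kw_trees)) {
    rows <- c(rows, list(tibble::tibble(
      term = "kruskal_wallis_trees", statistic = unname(x$kw_trees$statistic),
      p_value = x$kw_trees$p.value)))
  }
  if (!is.null(x$kw_sources)) {
    rows <- c(rows, list(tibble::tibble(
      term = "kruskal_wallis_sources",
      statistic = unname(x$kw_sources$statistic),
      p_value = x$kw_sources$p.value)))
  }
  if (!is.null(x$ols)) {
    cf <- summary(x$ols)$coefficients
    rows <- c(rows, list(tibble::tibble(
      term = paste0("ols_", rownames(cf)),
      statistic = cf[, "Estimate"], p_value = cf[, "Pr(>|t|)"])))
  }
  rows <- c(rows, list(tibble::tibble(
    term = c("frac_transport_beyond_3", "frac_locations_increase"),
    statistic = c(x$frac_transport_beyond_3, x$frac_locations_increase),
    p_value = NA_real_)))
  dplyr::bind_rows(rows)
}

#' @rdname tidy.toolscape_sweep_stats
#' @export
glance.toolscape_sweep_stats <- function(x, ...) {
  tibble::tibble(
    n_runs = x$n_runs,
    kw_chisq_trees = if (!is.null(x$kw_trees))
      unname(x$kw_trees$statistic) else NA_real_,
    kw_p_trees = if (!is.null(x$kw_trees)) x$kw_trees$p.value else NA_real_,
    kw_chisq_sources = if (!is.null(x$kw_sources))
      unname(x$kw_sources$statistic) else NA_real_,
    ols_r_squared = x$ols_r_squared,
    std_coef_trees = x$std_coef_trees,
    std_coef_sources = x$std_coef_sources,
    frac_transport_beyond_3 = x$frac_transport_beyond_3,
    frac_locations_increase = x$frac_locations_increase)
}
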