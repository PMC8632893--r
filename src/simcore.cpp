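// Simulation core: bounded (optionally toroidal) grid, sequential random
// activation of primates, stochastic tool breakage, tree turnover.
// All randomness is drawn from R's RNG so set.seed() on the R side fixes
// every trajectory. Draw order is documented in the methods vignette and
// must not be reordered: per step -- (1) one Fisher-Yates shuffle of the
// primate order, (2) per primate in that order: move draw, then bout draws
// (tree tie-break, material tie-break, mass draw if from a source, discard
// draw, break draw, fragment draw), (3) tree regrowth draws in tree-id order.

#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <algorithm>
using namespace Rcpp;

static inline int runif_int(int n) {
  // uniform on {0, ..., n-1}
  int k = (int)(unif_rand() * n);
  return k >= n ? n - 1 : k;
}

struct FragmentDist {
  int type;                 // 0 = lognormal mixture, 1 = empirical table
  double p_small;
  double small_meanlog, small_sdlog;
  double large_meanlog, large_sdlog;
  std::vector<double> table;

  double draw() const {
    if (type == 1) return table[runif_int((int)table.size())];
    if (unif_rand() < p_small)
      return std::exp(small_meanlog + small_sdlog * norm_rand());
    return std::exp(large_meanlog + large_sdlog * norm_rand());
  }
};

struct SimState {
  // config
  int W, H;
  bool torus;
  int n_primates, n_trees, n_sources;
  bool dynamic_trees;
  int tree_lifespan, regrow_radius, search_radius, interaction_radius,
      location_radius;
  double usable_threshold, baseline_break_prob;
  double initial_mass_mean, initial_mass_sd;
  FragmentDist fragdist;

  // primates
  std::vector<int> px, py;

  // sources (fixed)
  std::vector<int> sx, sy, sfrag;
  std::vector<int> source_grid;           // cell -> source index + 1, 0 = none

  // trees (live + dead, by id)
  std::vector<int> tx, ty, tage, tborn, tdeath, tparent; // tdeath -1 = alive
  std::vector<char> talive;
  std::vector<int> tree_grid;             // cell -> tree index + 1 (live only)
  std::vector<int> live_ids;              // ids of live trees

  // tools (every tool and fragment ever created)
  std::vector<double> mass, init_mass;
  std::vector<int> ox, oy, x_, y_, frag_, origin_src, parent_, uses_, created_;
  std::vector<char> is_frag;
  std::vector<std::vector<int> > cell_tools; // usable tools per cell

  int step_index;
  int n_regrow_widened;                   // regrow window had no free cell

  inline int cell(int x, int y) const { return y * W + x; }
  inline int wrap(int v, int m) const { int r = v % m; return r < 0 ? r + m : r; }

  bool in_grid(int x, int y) const {
    return x >= 0 && x < W && y >= 0 && y < H;
  }

  // resolve a possibly off-grid coordinate; returns false if unusable
  bool resolve(int &x, int &y) const {
    if (torus) { x = wrap(x, W); y = wrap(y, H); return true; }
    return in_grid(x, y);
  }

  bool usable(int t) const { return mass[t] >= usable_threshold; }

  // cell lists and the live-tree list are kept in ascending id order so a
  // serialised world resumes with the exact RNG-draw mapping it would have
  // had in a continuous run
  void add_to_cell(int t) {
    std::vector<int> &v = cell_tools[cell(x_[t], y_[t])];
    v.insert(std::lower_bound(v.begin(), v.end(), t), t);
  }

  void remove_from_cell(int t) {
    std::vector<int> &v = cell_tools[cell(x_[t], y_[t])];
    std::vector<int>::iterator it =
      std::lower_bound(v.begin(), v.end(), t);
    if (it != v.end() && *it == t) v.erase(it);
  }
};

// ---- spatial queries ------------------------------------------------------

// nearest live tree within interaction_radius (Chebyshev), ties random
static int nearest_live_tree(const SimState &S, int px, int py) {
  for (int r = 0; r <= S.interaction_radius; ++r) {
    std::vector<int> hits;
    for (int dy = -r; dy <= r; ++dy) {
      for (int dx = -r; dx <= r; ++dx) {
        if (std::max(std::abs(dx), std::abs(dy)) != r) continue;
        int x = px + dx, y = py + dy;
        if (!S.resolve(x, y)) continue;
        int id = S.tree_grid[S.cell(x, y)];
        if (id) hits.push_back(id - 1);
      }
    }
    if (!hits.empty())
      return hits.size() == 1 ? hits[0] : hits[runif_int((int)hits.size())];
  }
  return -1;
}

// nearest source or usable tool within search_radius; sources and tools are
// pooled at each ring, ties uniform. kind: 0 source, 1 tool; -1 if none.
static void find_material_impl(const SimState &S, int px, int py,
                               int &kind, int &index) {
  kind = -1; index = -1;
  for (int r = 0; r <= S.search_radius; ++r) {
    std::vector<int> kinds, idxs;
    for (int dy = -r; dy <= r; ++dy) {
      for (int dx = -r; dx <= r; ++dx) {
        if (std::max(std::abs(dx), std::abs(dy)) != r) continue;
        int x = px + dx, y = py + dy;
        if (!S.resolve(x, y)) continue;
        int c = S.cell(x, y);
        int sid = S.source_grid[c];
        if (sid) { kinds.push_back(0); idxs.push_back(sid - 1); }
        const std::vector<int> &tv = S.cell_tools[c];
        for (size_t i = 0; i < tv.size(); ++i) {
          kinds.push_back(1); idxs.push_back(tv[i]);
        }
      }
    }
    if (!kinds.empty()) {
      int k = kinds.size() == 1 ? 0 : runif_int((int)kinds.size());
      kind = kinds[k]; index = idxs[k];
      return;
    }
  }
}

static int count_locations_impl(const SimState &S) {
  int n = 0, R = S.location_radius;
  for (size_t i = 0; i < S.live_ids.size(); ++i) {
    int id = S.live_ids[i];
    int cx = S.tx[id], cy = S.ty[id];
    bool found = false;
    for (int dy = -R; dy <= R && !found; ++dy) {
      for (int dx = -R; dx <= R && !found; ++dx) {
        int x = cx + dx, y = cy + dy;
        if (!S.resolve(x, y)) continue;
        int c = S.cell(x, y);
        if (S.source_grid[c] || !S.cell_tools[c].empty()) found = true;
      }
    }
    if (found) ++n;
  }
  return n;
}

static double draw_initial_mass_impl(double mean, double sd, double thr) {
  if (sd <= 0) return mean;
  for (int i = 0; i < 10000000; ++i) {
    double m = mean + sd * norm_rand();
    if (m >= thr) return m;
  }
  Rcpp::stop("initial-mass rejection sampling failed: mean far below usable_threshold");
  return NA_REAL; // not reached
}

// ---- state (de)serialisation ---------------------------------------------

static FragmentDist parse_fragdist(List fd) {
  FragmentDist d;
  std::string type = as<std::string>(fd["type"]);
  if (type == "mixture") {
    d.type = 0;
    d.p_small = as<double>(fd["p_small"]);
    d.small_meanlog = as<double>(fd["small_meanlog"]);
    d.small_sdlog = as<double>(fd["small_sdlog"]);
    d.large_meanlog = as<double>(fd["large_meanlog"]);
    d.large_sdlog = as<double>(fd["large_sdlog"]);
  } else {
    d.type = 1;
    d.table = as<std::vector<double> >(fd["masses"]);
    if (d.table.empty()) Rcpp::stop("empirical fragment table is empty");
  }
  return d;
}

static void load_config(SimState &S, List cfg) {
  S.W = as<int>(cfg["width"]);  S.H = as<int>(cfg["height"]);
  S.torus = as<bool>(cfg["torus"]);
  S.n_primates = as<int>(cfg["n_primates"]);
  S.n_trees = as<int>(cfg["n_trees"]);
  S.n_sources = as<int>(cfg["n_sources"]);
  S.dynamic_trees = as<bool>(cfg["dynamic_trees"]);
  S.tree_lifespan = as<int>(cfg["tree_lifespan"]);
  S.regrow_radius = as<int>(cfg["regrow_radius"]);
  S.search_radius = as<int>(cfg["search_radius"]);
  S.interaction_radius = as<int>(cfg["interaction_radius"]);
  S.location_radius = as<int>(cfg["location_radius"]);
  S.usable_threshold = as<double>(cfg["usable_threshold"]);
  S.baseline_break_prob = as<double>(cfg["baseline_break_prob"]);
  S.initial_mass_mean = as<double>(cfg["initial_mass_mean"]);
  S.initial_mass_sd = as<double>(cfg["initial_mass_sd"]);
  S.fragdist = parse_fragdist(cfg["fragment_distribution"]);
  S.source_grid.assign((size_t)S.W * S.H, 0);
  S.tree_grid.assign((size_t)S.W * S.H, 0);
  S.cell_tools.assign((size_t)S.W * S.H, std::vector<int>());
  S.step_index = 0;
  S.n_regrow_widened = 0;
}

// place entities at random unique cells (sources + trees mutually exclusive)
static void init_entities(SimState &S, List cfg) {
  IntegerVector frag_levels = cfg["fragility_levels"];
  bool preset_sources = cfg.containsElementNamed("preset_sources") &&
                        !Rf_isNull(cfg["preset_sources"]);
  bool preset_trees = cfg.containsElementNamed("preset_trees") &&
                      !Rf_isNull(cfg["preset_trees"]);
  bool preset_primates = cfg.containsElementNamed("preset_primates") &&
                         !Rf_isNull(cfg["preset_primates"]);

  if (preset_sources) {
    List ps = cfg["preset_sources"];
    IntegerVector xs = ps["x"], ys = ps["y"], fr = ps["fragility"];
    for (int i = 0; i < xs.size(); ++i) {
      S.sx.push_back(xs[i]); S.sy.push_back(ys[i]); S.sfrag.push_back(fr[i]);
      S.source_grid[S.cell(xs[i], ys[i])] = i + 1;
    }
    S.n_sources = (int)S.sx.size();
  } else {
    for (int i = 0; i < S.n_sources; ++i) {
      int x, y;
      do { x = runif_int(S.W); y = runif_int(S.H); }
      while (S.source_grid[S.cell(x, y)]);
      S.sx.push_back(x); S.sy.push_back(y);
      S.sfrag.push_back(frag_levels[runif_int(frag_levels.size())]);
      S.source_grid[S.cell(x, y)] = i + 1;
    }
  }

  if (preset_trees) {
    List pt = cfg["preset_trees"];
    IntegerVector xs = pt["x"], ys = pt["y"];
    for (int i = 0; i < xs.size(); ++i) {
      S.tx.push_back(xs[i]); S.ty.push_back(ys[i]);
      S.tage.push_back(1 + runif_int(S.tree_lifespan));
      S.tborn.push_back(-S.tage[i]); S.tdeath.push_back(-1);
      S.tparent.push_back(-1); S.talive.push_back(1);
      S.tree_grid[S.cell(xs[i], ys[i])] = i + 1;
      S.live_ids.push_back(i);
    }
    S.n_trees = (int)S.tx.size();
  } else {
    for (int i = 0; i < S.n_trees; ++i) {
      int x, y;
      do { x = runif_int(S.W); y = runif_int(S.H); }
      while (S.source_grid[S.cell(x, y)] || S.tree_grid[S.cell(x, y)]);
      S.tx.push_back(x); S.ty.push_back(y);
      S.tage.push_back(1 + runif_int(S.tree_lifespan));
      S.tborn.push_back(-S.tage[i]); S.tdeath.push_back(-1);
      S.tparent.push_back(-1); S.talive.push_back(1);
      S.tree_grid[S.cell(x, y)] = i + 1;
      S.live_ids.push_back(i);
    }
  }

  if (preset_primates) {
    List pp = cfg["preset_primates"];
    IntegerVector xs = pp["x"], ys = pp["y"];
    for (int i = 0; i < xs.size(); ++i) {
      S.px.push_back(xs[i]); S.py.push_back(ys[i]);
    }
    S.n_primates = (int)S.px.size();
  } else {
    for (int i = 0; i < S.n_primates; ++i) {
      S.px.push_back(runif_int(S.W)); S.py.push_back(runif_int(S.H));
    }
  }
}

static void load_state(SimState &S, List st) {
  List pr = st["primates"];
  S.px = as<std::vector<int> >(pr["x"]);
  S.py = as<std::vector<int> >(pr["y"]);
  S.n_primates = (int)S.px.size();

  List so = st["sources"];
  S.sx = as<std::vector<int> >(so["x"]);
  S.sy = as<std::vector<int> >(so["y"]);
  S.sfrag = as<std::vector<int> >(so["fragility"]);
  S.n_sources = (int)S.sx.size();
  for (int i = 0; i < S.n_sources; ++i)
    S.source_grid[S.cell(S.sx[i], S.sy[i])] = i + 1;

  List tr = st["trees"];
  S.tx = as<std::vector<int> >(tr["x"]);
  S.ty = as<std::vector<int> >(tr["y"]);
  S.tage = as<std::vector<int> >(tr["age"]);
  S.tborn = as<std::vector<int> >(tr["born_step"]);
  S.tdeath = as<std::vector<int> >(tr["death_step"]);
  S.tparent = as<std::vector<int> >(tr["parent_tree_id"]);
  IntegerVector alv = tr["alive"];
  for (int i = 0; i < alv.size(); ++i) {
    S.talive.push_back((char)alv[i]);
    if (alv[i]) {
      S.tree_grid[S.cell(S.tx[i], S.ty[i])] = i + 1;
      S.live_ids.push_back(i);
    }
  }

  List tl = st["tools"];
  S.mass = as<std::vector<double> >(tl["mass"]);
  S.init_mass = as<std::vector<double> >(tl["initial_mass"]);
  S.x_ = as<std::vector<int> >(tl["x"]);
  S.y_ = as<std::vector<int> >(tl["y"]);
  S.ox = as<std::vector<int> >(tl["origin_x"]);
  S.oy = as<std::vector<int> >(tl["origin_y"]);
  S.frag_ = as<std::vector<int> >(tl["fragility"]);
  S.origin_src = as<std::vector<int> >(tl["origin_source_id"]);
  S.parent_ = as<std::vector<int> >(tl["parent_id"]);
  S.uses_ = as<std::vector<int> >(tl["n_uses"]);
  S.created_ = as<std::vector<int> >(tl["created_step"]);
  IntegerVector isf = tl["is_fragment"];
  for (int i = 0; i < isf.size(); ++i) {
    S.is_frag.push_back((char)isf[i]);
    if (S.mass[i] >= S.usable_threshold)
      S.cell_tools[S.cell(S.x_[i], S.y_[i])].push_back(i);
  }
  S.step_index = as<int>(st["step_index"]);
}

// ---- per-step update ------------------------------------------------------

struct BoutLog {
  std::vector<int> step, primate, tool, kind, mx, my, tree_x, tree_y,
      dx_, dy_, mat_tree_dist;
  std::vector<double> sel_mass, frag_mass;
  std::vector<int> broke;
};

static void do_bout(SimState &S, int p, int tree, int kind, int index,
                    BoutLog *log) {
  int mx, my; double sel_mass;
  int tool;
  if (kind == 0) { // acquire a fresh tool from a source
    mx = S.sx[index]; my = S.sy[index];
    double m = draw_initial_mass_impl(S.initial_mass_mean, S.initial_mass_sd,
                                      S.usable_threshold);
    tool = (int)S.mass.size();
    S.mass.push_back(m); S.init_mass.push_back(m);
    S.x_.push_back(mx); S.y_.push_back(my);
    S.ox.push_back(mx); S.oy.push_back(my);
    S.frag_.push_back(S.sfrag[index]);
    S.origin_src.push_back(index);
    S.parent_.push_back(-1);
    S.uses_.push_back(0);
    S.created_.push_back(S.step_index + 1);
    S.is_frag.push_back(0);
    sel_mass = NA_REAL;
  } else {       // re-use a discarded usable tool
    tool = index;
    mx = S.x_[tool]; my = S.y_[tool];
    sel_mass = S.mass[tool];
    S.remove_from_cell(tool);
  }

  // discard cell: uniform over tree cell + in-grid Moore neighbours
  int cand_x[9], cand_y[9], nc = 0;
  for (int dy = -1; dy <= 1; ++dy)
    for (int dx = -1; dx <= 1; ++dx) {
      int x = S.tx[tree] + dx, y = S.ty[tree] + dy;
      if (S.resolve(x, y)) { cand_x[nc] = x; cand_y[nc] = y; ++nc; }
    }
  int k = runif_int(nc);
  S.x_[tool] = cand_x[k]; S.y_[tool] = cand_y[k];
  S.uses_[tool] += 1;

  // breakage
  double pbr = S.baseline_break_prob + S.frag_[tool] / 100.0;
  if (pbr > 1) pbr = 1;
  int broke = 0; double fm = NA_REAL;
  if (unif_rand() < pbr) {
    broke = 1;
    fm = S.fragdist.draw();
    if (fm > S.mass[tool]) fm = S.mass[tool];
    S.mass[tool] -= fm;
    int f = (int)S.mass.size();
    S.mass.push_back(fm); S.init_mass.push_back(fm);
    S.x_.push_back(S.x_[tool]); S.y_.push_back(S.y_[tool]);
    S.ox.push_back(S.ox[tool]); S.oy.push_back(S.oy[tool]);
    S.frag_.push_back(S.frag_[tool]);
    S.origin_src.push_back(S.origin_src[tool]);
    S.parent_.push_back(tool);
    S.uses_.push_back(0);
    S.created_.push_back(S.step_index + 1);
    S.is_frag.push_back(1);
    if (fm >= S.usable_threshold)
      S.add_to_cell(f);
  }
  if (S.usable(tool))
    S.add_to_cell(tool);

  if (log) {
    log->step.push_back(S.step_index + 1);
    log->primate.push_back(p);
    log->tool.push_back(tool);
    log->kind.push_back(kind);
    log->mx.push_back(mx); log->my.push_back(my);
    log->tree_x.push_back(S.tx[tree]); log->tree_y.push_back(S.ty[tree]);
    log->dx_.push_back(S.x_[tool]); log->dy_.push_back(S.y_[tool]);
    int d;
    if (S.torus) {
      int ax = std::abs(mx - S.tx[tree]); ax = std::min(ax, S.W - ax);
      int ay = std::abs(my - S.ty[tree]); ay = std::min(ay, S.H - ay);
      d = std::max(ax, ay);
    } else {
      d = std::max(std::abs(mx - S.tx[tree]), std::abs(my - S.ty[tree]));
    }
    log->mat_tree_dist.push_back(d);
    log->sel_mass.push_back(sel_mass);
    log->broke.push_back(broke);
    log->frag_mass.push_back(fm);
  }
}

static void advance_trees(SimState &S) {
  if (!S.dynamic_trees) return;   // static condition: ages frozen, no turnover
  std::vector<int> dead;
  for (size_t i = 0; i < S.live_ids.size(); ++i) {
    int id = S.live_ids[i];
    S.tage[id] += 1;
    if (S.tage[id] >= S.tree_lifespan) dead.push_back(id);
  }
  for (size_t i = 0; i < dead.size(); ++i) {
    int id = dead[i];
    S.talive[id] = 0;
    S.tdeath[id] = S.step_index + 1;
    S.tree_grid[S.cell(S.tx[id], S.ty[id])] = 0;
    S.live_ids.erase(std::lower_bound(S.live_ids.begin(),
                                      S.live_ids.end(), id));

    // replacement within regrow_radius, excluding live-tree and source cells
    std::vector<int> cx, cy;
    int R = S.regrow_radius;
    for (int dy = -R; dy <= R; ++dy)
      for (int dx = -R; dx <= R; ++dx) {
        int x = S.tx[id] + dx, y = S.ty[id] + dy;
        if (!S.resolve(x, y)) continue;
        int c = S.cell(x, y);
        if (!S.tree_grid[c] && !S.source_grid[c]) { cx.push_back(x); cy.push_back(y); }
      }
    if (cx.empty()) {  // widen to the full grid
      S.n_regrow_widened += 1;
      for (int y = 0; y < S.H; ++y)
        for (int x = 0; x < S.W; ++x) {
          int c = S.cell(x, y);
          if (!S.tree_grid[c] && !S.source_grid[c]) { cx.push_back(x); cy.push_back(y); }
        }
      if (cx.empty()) Rcpp::stop("no free cell anywhere for tree regrowth");
    }
    int k = runif_int((int)cx.size());
    int nid = (int)S.tx.size();
    S.tx.push_back(cx[k]); S.ty.push_back(cy[k]);
    S.tage.push_back(0);
    S.tborn.push_back(S.step_index + 1);
    S.tdeath.push_back(-1);
    S.tparent.push_back(id);
    S.talive.push_back(1);
    S.tree_grid[S.cell(cx[k], cy[k])] = nid + 1;
    S.live_ids.push_back(nid);
  }
}

static void move_primate_impl(SimState &S, int p) {
  int cand_x[8], cand_y[8], nc = 0;
  for (int dy = -1; dy <= 1; ++dy)
    for (int dx = -1; dx <= 1; ++dx) {
      if (!dx && !dy) continue;
      int x = S.px[p] + dx, y = S.py[p] + dy;
      if (S.resolve(x, y)) { cand_x[nc] = x; cand_y[nc] = y; ++nc; }
    }
  int k = runif_int(nc);
  S.px[p] = cand_x[k]; S.py[p] = cand_y[k];
}

static void world_step_impl(SimState &S, std::vector<int> &order, BoutLog *log) {
  // fresh shuffle of the activation order, always from the identity
  // permutation so a resumed world replays the same schedule
  for (int i = 0; i < (int)order.size(); ++i) order[i] = i;
  for (int i = (int)order.size() - 1; i > 0; --i) {
    int j = runif_int(i + 1);
    std::swap(order[i], order[j]);
  }
  for (size_t i = 0; i < order.size(); ++i) {
    int p = order[i];
    move_primate_impl(S, p);
    int tree = nearest_live_tree(S, S.px[p], S.py[p]);
    if (tree < 0) continue;
    int kind, index;
    find_material_impl(S, S.px[p], S.py[p], kind, index);
    if (kind < 0) continue;    // nothing in reach: primate idles
    do_bout(S, p, tree, kind, index, log);
  }
  advance_trees(S);
  S.step_index += 1;
}

// ---- result marshalling ---------------------------------------------------

static double max_displacement_now(const SimState &S) {
  int best = 0;
  for (size_t t = 0; t < S.mass.size(); ++t) {
    if (S.is_frag[t]) continue;
    int ax = std::abs(S.x_[t] - S.ox[t]);
    int ay = std::abs(S.y_[t] - S.oy[t]);
    if (S.torus) { ax = std::min(ax, S.W - ax); ay = std::min(ay, S.H - ay); }
    int d = std::max(ax, ay);
    if (d > best) best = d;
  }
  return best;
}

static List export_state(const SimState &S) {
  int nt = (int)S.tx.size();
  IntegerVector t_id(nt), t_x(nt), t_y(nt), t_age(nt), t_born(nt),
      t_death(nt), t_parent(nt), t_alive(nt);
  for (int i = 0; i < nt; ++i) {
    t_id[i] = i; t_x[i] = S.tx[i]; t_y[i] = S.ty[i]; t_age[i] = S.tage[i];
    t_born[i] = S.tborn[i]; t_death[i] = S.tdeath[i];
    t_parent[i] = S.tparent[i]; t_alive[i] = S.talive[i];
  }
  int ntool = (int)S.mass.size();
  IntegerVector l_id(ntool), l_x(ntool), l_y(ntool), l_ox(ntool), l_oy(ntool),
      l_frag(ntool), l_src(ntool), l_parent(ntool), l_uses(ntool),
      l_created(ntool), l_isf(ntool);
  NumericVector l_mass(ntool), l_init(ntool);
  for (int i = 0; i < ntool; ++i) {
    l_id[i] = i; l_x[i] = S.x_[i]; l_y[i] = S.y_[i];
    l_ox[i] = S.ox[i]; l_oy[i] = S.oy[i];
    l_frag[i] = S.frag_[i]; l_src[i] = S.origin_src[i];
    l_parent[i] = S.parent_[i]; l_uses[i] = S.uses_[i];
    l_created[i] = S.created_[i]; l_isf[i] = S.is_frag[i];
    l_mass[i] = S.mass[i]; l_init[i] = S.init_mass[i];
  }
  return List::create(
    _["step_index"] = S.step_index,
    _["primates"] = List::create(_["x"] = wrap(S.px), _["y"] = wrap(S.py)),
    _["sources"] = List::create(_["x"] = wrap(S.sx), _["y"] = wrap(S.sy),
                                _["fragility"] = wrap(S.sfrag)),
    _["trees"] = List::create(_["tree_id"] = t_id, _["x"] = t_x, _["y"] = t_y,
                              _["age"] = t_age, _["alive"] = t_alive,
                              _["born_step"] = t_born, _["death_step"] = t_death,
                              _["parent_tree_id"] = t_parent),
    _["tools"] = List::create(_["tool_id"] = l_id, _["x"] = l_x, _["y"] = l_y,
                              _["origin_x"] = l_ox, _["origin_y"] = l_oy,
                              _["mass"] = l_mass, _["initial_mass"] = l_init,
                              _["fragility"] = l_frag,
                              _["origin_source_id"] = l_src,
                              _["parent_id"] = l_parent, _["n_uses"] = l_uses,
                              _["is_fragment"] = l_isf,
                              _["created_step"] = l_created),
    _["n_regrow_widened"] = S.n_regrow_widened);
}

// [[Rcpp::export]]
List cpp_sim(List cfg, Nullable<List> state, int n_steps, int record_every,
             bool record_bouts) {
  SimState S;
  load_config(S, cfg);
  if (state.isNotNull()) load_state(S, as<List>(state));
  else init_entities(S, cfg);

  BoutLog log;
  BoutLog *logp = record_bouts ? &log : (BoutLog *)0;
  std::vector<int> order(S.n_primates);
  for (int i = 0; i < S.n_primates; ++i) order[i] = i;

  std::vector<int> ts_step, ts_loc, ts_live;
  std::vector<double> ts_disp;
  ts_step.push_back(S.step_index);
  ts_loc.push_back(count_locations_impl(S));
  ts_live.push_back((int)S.live_ids.size());
  ts_disp.push_back(max_displacement_now(S));

  int target = S.step_index + n_steps;
  while (S.step_index < target) {
    world_step_impl(S, order, logp);
    if (S.step_index % record_every == 0 || S.step_index == target) {
      ts_step.push_back(S.step_index);
      ts_loc.push_back(count_locations_impl(S));
      ts_live.push_back((int)S.live_ids.size());
      ts_disp.push_back(max_displacement_now(S));
    }
    if (S.step_index % 2048 == 0) Rcpp::checkUserInterrupt();
  }

  List out = List::create(
    _["state"] = export_state(S),
    _["timeseries"] = List::create(
      _["step"] = wrap(ts_step), _["n_locations"] = wrap(ts_loc),
      _["n_live_trees"] = wrap(ts_live), _["max_displacement"] = wrap(ts_disp)));
  if (record_bouts)
    out["bouts"] = List::create(
      _["step"] = wrap(log.step), _["primate_id"] = wrap(log.primate),
      _["tool_id"] = wrap(log.tool), _["material_kind"] = wrap(log.kind),
      _["material_x"] = wrap(log.mx), _["material_y"] = wrap(log.my),
      _["material_mass"] = wrap(log.sel_mass),
      _["tree_x"] = wrap(log.tree_x), _["tree_y"] = wrap(log.tree_y),
      _["x"] = wrap(log.dx_), _["y"] = wrap(log.dy_),
      _["material_tree_distance"] = wrap(log.mat_tree_dist),
      _["broke"] = wrap(log.broke), _["fragment_mass"] = wrap(log.frag_mass));
  return out;
}

// ---- standalone query wrappers (same code paths as the run loop) ----------

// builds a minimal state around explicit entity tables
static SimState query_state(int width, int height, bool torus,
                            IntegerVector sx, IntegerVector sy,
                            IntegerVector tlx, IntegerVector tly,
                            NumericVector tlm,
                            int search_radius, int interaction_radius,
                            int location_radius, double threshold) {
  SimState S;
  S.W = width; S.H = height; S.torus = torus;
  S.search_radius = search_radius;
  S.interaction_radius = interaction_radius;
  S.location_radius = location_radius;
  S.usable_threshold = threshold;
  S.source_grid.assign((size_t)width * height, 0);
  S.tree_grid.assign((size_t)width * height, 0);
  S.cell_tools.assign((size_t)width * height, std::vector<int>());
  for (int i = 0; i < sx.size(); ++i) {
    S.sx.push_back(sx[i]); S.sy.push_back(sy[i]);
    S.source_grid[S.cell(sx[i], sy[i])] = i + 1;
  }
  for (int i = 0; i < tlx.size(); ++i) {
    S.mass.push_back(tlm[i]);
    S.x_.push_back(tlx[i]); S.y_.push_back(tly[i]);
    if (tlm[i] >= threshold)
      S.cell_tools[S.cell(tlx[i], tly[i])].push_back(i);
  }
  return S;
}

// [[Rcpp::export]]
List cpp_find_material(int px, int py, int width, int height, bool torus,
                       IntegerVector source_x, IntegerVector source_y,
                       IntegerVector tool_x, IntegerVector tool_y,
                       NumericVector tool_mass,
                       int search_radius, double threshold) {
  SimState S = query_state(width, height, torus, source_x, source_y,
                           tool_x, tool_y, tool_mass,
                           search_radius, 1, 3, threshold);
  int kind, index;
  find_material_impl(S, px, py, kind, index);
  return List::create(_["kind"] = kind, _["index"] = index);
}

// [[Rcpp::export]]
int cpp_count_locations(int width, int height, bool torus,
                        IntegerVector tree_x, IntegerVector tree_y,
                        IntegerVector source_x, IntegerVector source_y,
                        IntegerVector tool_x, IntegerVector tool_y,
                        NumericVector tool_mass,
                        int location_radius, double threshold) {
  SimState S = query_state(width, height, torus, source_x, source_y,
                           tool_x, tool_y, tool_mass, 2, 1,
                           location_radius, threshold);
  for (int i = 0; i < tree_x.size(); ++i) {
    S.tx.push_back(tree_x[i]); S.ty.push_back(tree_y[i]);
    S.live_ids.push_back(i);
  }
  return count_locations_impl(S);
}

// [[Rcpp::export]]
int cpp_nearest_live_tree(int px, int py, int width, int height, bool torus,
                          IntegerVector tree_x, IntegerVector tree_y,
                          IntegerVector alive, int interaction_radius) {
  SimState S;
  S.W = width; S.H = height; S.torus = torus;
  S.interaction_radius = interaction_radius;
  S.tree_grid.assign((size_t)width * height, 0);
  for (int i = 0; i < tree_x.size(); ++i) {
    S.tx.push_back(tree_x[i]); S.ty.push_back(tree_y[i]);
    if (alive[i]) S.tree_grid[S.cell(tree_x[i], tree_y[i])] = i + 1;
  }
  return nearest_live_tree(S, px, py);
}

// [[Rcpp::export]]
NumericVector cpp_draw_initial_mass(int n, double mean, double sd,
                                    double threshold) {
  NumericVector out(n);
  for (int i = 0; i < n; ++i)
    out[i] = draw_initial_mass_impl(mean, sd, threshold);
  return out;
}

// [[Rcpp::export]]
NumericVector cpp_draw_fragment_mass(int n, List fragment_distribution) {
  FragmentDist d = parse_fragdist(fragment_distribution);
  NumericVector out(n);
  for (int i = 0; i < n; ++i) out[i] = d.draw();
  return out;
}

// [[Rcpp::export]]
IntegerMatrix cpp_random_moves(int n, int x, int y, int width, int height,
                               bool torus) {
  // n independent single-step moves from (x, y); used to test the
  // movement kernel in isolation
  SimState S;
  S.W = width; S.H = height; S.torus = torus;
  IntegerMatrix out(n, 2);
  for (int i = 0; i < n; ++i) {
    S.px.assign(1, x); S.py.assign(1, y);
    move_primate_impl(S, 0);
    out(i, 0) = S.px[0]; out(i, 1) = S.py[0];
  }
  return out;
}
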