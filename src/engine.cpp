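// Discrete-event core of the hallmark cellular-automaton tumor model.
//
// All randomness is drawn from R's global RNG stream (unif_rand), so a single
// set.seed() on the R side makes whole simulations reproducible. Events live
// in a binary heap keyed by (iteration time, insertion sequence); dead cells
// are invalidated lazily when their event is popped.

#include <Rcpp.h>
#include <queue>
#include <vector>
#include <array>
#include <algorithm>
#include <cstdint>
#include <climits>

using namespace Rcpp;

// hallmark flag bits
static const int H_SG = 1;   // self-growth
static const int H_IGI = 2;  // ignore growth inhibit
static const int H_EA = 4;   // evade apoptosis
static const int H_EI = 8;   // effective immortality
static const int H_GI = 16;  // genetic instability

enum Outcome {
  OUT_EMPTY_QUEUE = -1,
  OUT_STALE = 0,
  OUT_DIED_RANDOM = 1,
  OUT_DIED_DAMAGE = 2,
  OUT_DIED_TELOMERE = 3,
  OUT_DIED_COMPETITION = 4,
  OUT_DIVIDED = 5,
  OUT_QUIESCENT = 6
};

struct Cell {
  int site;       // linear site index, -1 when dead
  int telomere;
  int ndiv;       // divisions along this lineage (telomere ledger)
  double mdenom;  // per-cell hallmark mutation denominator m
  uint8_t flags;
  uint8_t csc;
};

struct Event {
  int time;
  int cell;
  long long seq;
};

struct EventCmp {
  bool operator()(const Event& a, const Event& b) const {
    if (a.time != b.time) return a.time > b.time;
    return a.seq > b.seq;  // FIFO among ties
  }
};

static inline int rand_int(int lo, int hi) {
  // uniform on {lo, ..., hi}
  int r = lo + (int)(unif_rand() * (double)(hi - lo + 1));
  if (r > hi) r = hi;
  return r;
}

class Engine {
public:
  int side, margin, n_sites;
  bool moore;
  double a, e, g, gi_factor, m0, p_s;
  int tl0, dmin, dmax;
  bool igi_failure_kills;   // competition loser dies (true) or merely requeues
  bool csc_exempt_random;   // CSCs skip the random-death test
  bool csc_protected;       // CSCs cannot be killed by IGI competition
  bool csc_daughter_mut;    // asymmetric daughters also get a 1/m mutation draw

  std::vector<int> occ;     // site -> cell id, -1 = empty
  std::vector<Cell> cells;  // id -> cell (ids never reused)
  std::priority_queue<Event, std::vector<Event>, EventCmp> pq;
  long long seq;
  int completed;            // completed iterations
  int last_time;            // time of last processed (non-stale) event
  bool order_ok;

  std::vector<std::array<int,3> > offsets;

  // per-iteration counters (reset when a row is recorded)
  int it_asym, it_sym, it_kills, it_drand, it_ddam, it_dtel, it_dcomp, it_div;
  // cumulative counters (doubles: safe to return to R)
  double ev_live, ev_stale, c_drand, c_ddam, c_dtel, c_dcomp, c_div, c_quiesc,
    comp_att, comp_succ, mut_opp_base, mut_flip_base, mut_opp_gi, mut_flip_gi,
    c_sym, c_asym, c_kills;

  Engine(int side_, int margin_, bool moore_, List par)
    : side(side_), margin(margin_), n_sites(side_*side_*side_), moore(moore_) {
    a = as<double>(par["a"]);
    e = as<double>(par["e"]);
    g = as<double>(par["g"]);
    gi_factor = as<double>(par["gi_factor"]);
    m0 = as<double>(par["m"]);
    p_s = as<double>(par["p_s"]);
    tl0 = as<int>(par["tl0"]);
    dmin = as<int>(par["delay_min"]);
    dmax = as<int>(par["delay_max"]);
    igi_failure_kills = as<bool>(par["igi_failure_kills"]);
    csc_exempt_random = as<bool>(par["csc_exempt_random_death"]);
    csc_protected = as<bool>(par["csc_protected_from_competition"]);
    csc_daughter_mut = as<bool>(par["csc_daughter_mutations"]);
    occ.assign(n_sites, -1);
    seq = 0; completed = 0; last_time = 0; order_ok = true;
    reset_iter_counters();
    ev_live = ev_stale = c_drand = c_ddam = c_dtel = c_dcomp = c_div = c_quiesc = 0;
    comp_att = comp_succ = mut_opp_base = mut_flip_base = mut_opp_gi = mut_flip_gi = 0;
    c_sym = c_asym = c_kills = 0;
    for (int dz = -1; dz <= 1; ++dz)
      for (int dy = -1; dy <= 1; ++dy)
        for (int dx = -1; dx <= 1; ++dx) {
          if (dx == 0 && dy == 0 && dz == 0) continue;
          if (!moore && (std::abs(dx) + std::abs(dy) + std::abs(dz) != 1)) continue;
          std::array<int,3> o = {{dx, dy, dz}};
          offsets.push_back(o);
        }
  }

  void reset_iter_counters() {
    it_asym = it_sym = it_kills = it_drand = it_ddam = it_dtel = it_dcomp = it_div = 0;
  }

  inline void decode(int s, int& x, int& y, int& z) const {
    x = s % side; y = (s / side) % side; z = s / (side * side);
  }

  inline bool in_region(int s) const {
    if (margin == 0) return true;
    int x, y, z; decode(s, x, y, z);
    int hi = side - 1 - margin;
    return x >= margin && x <= hi && y >= margin && y <= hi &&
           z >= margin && z <= hi;
  }

  // fill nb with in-bounds neighbor site indices; returns count
  inline int neighbor_sites(int s, int* nb) const {
    int x, y, z; decode(s, x, y, z);
    int n = 0;
    for (size_t k = 0; k < offsets.size(); ++k) {
      int nx = x + offsets[k][0], ny = y + offsets[k][1], nz = z + offsets[k][2];
      if (nx < 0 || nx >= side || ny < 0 || ny >= side || nz < 0 || nz >= side)
        continue;
      nb[n++] = nx + side * (ny + side * nz);
    }
    return n;
  }

  int new_cell(int site, uint8_t flags, uint8_t csc, int telomere, int ndiv,
               double mdenom) {
    Cell c; c.site = site; c.flags = flags; c.csc = csc;
    c.telomere = telomere; c.ndiv = ndiv; c.mdenom = mdenom;
    cells.push_back(c);
    int id = (int)cells.size() - 1;
    occ[site] = id;
    return id;
  }

  inline void kill_cell(int id) {
    occ[cells[id].site] = -1;
    cells[id].site = -1;
  }

  void schedule(int id, int base) {
    Event ev; ev.time = base + rand_int(dmin, dmax); ev.cell = id; ev.seq = seq++;
    pq.push(ev);
  }

  void fill_healthy() {
    for (int s = 0; s < n_sites; ++s) {
      if (occ[s] >= 0) continue;
      int id = new_cell(s, 0, 0, tl0, 0, m0);
      schedule(id, completed);
    }
  }

  inline double mut_prob(uint8_t flags, double mdenom) const {
    if (flags & H_GI) return std::min(1.0, gi_factor / mdenom);
    return 1.0 / mdenom;
  }

  void mutate(int id, double p, bool gi_on) {
    Cell& c = cells[id];
    for (int b = 0; b < 5; ++b) {
      uint8_t bit = (uint8_t)(1 << b);
      if (c.flags & bit) continue;
      if (gi_on) ++mut_opp_gi; else ++mut_opp_base;
      if (unif_rand() < p) {
        c.flags |= bit;
        if (gi_on) ++mut_flip_gi; else ++mut_flip_base;
      }
    }
  }

  // mother passed all tests; target must be empty
  void do_divide(int mid, int target, int t) {
    Cell& m = cells[mid];
    uint8_t pre = m.flags;
    bool gi_on = (pre & H_GI) != 0;
    double p = mut_prob(pre, m.mdenom);
    int tel = m.telomere > 0 ? m.telomere - 1 : 0;
    m.telomere = tel;
    m.ndiv += 1;
    int did = new_cell(target, pre, 0, tel, m.ndiv, m.mdenom);
    mutate(mid, p, gi_on);
    mutate(did, p, gi_on);
    schedule(mid, t);
    schedule(did, t);
    c_div += 1; it_div += 1;
  }

  int compete(int id, int t, const int* nb, int nn) {
    comp_att += 1;
    if (unif_rand() < 1.0 / g) {
      int v = nb[rand_int(0, nn - 1)];
      int vid = occ[v];
      bool blocked = (vid >= 0 && cells[vid].csc && csc_protected);
      if (!blocked) {
        comp_succ += 1;
        if (vid >= 0) { kill_cell(vid); c_dcomp += 1; it_dcomp += 1; }
        do_divide(id, v, t);
        return OUT_DIVIDED;
      }
    }
    if (igi_failure_kills) {
      kill_cell(id); c_dcomp += 1; it_dcomp += 1;
      return OUT_DIED_COMPETITION;
    }
    schedule(id, t); c_quiesc += 1;
    return OUT_QUIESCENT;
  }

  int csc_step(int id, int t) {
    Cell& c = cells[id];
    if (!csc_exempt_random && unif_rand() < 1.0 / a) {
      kill_cell(id); c_drand += 1; it_drand += 1;
      return OUT_DIED_RANDOM;
    }
    int nb[26], emp[26];
    int nn = neighbor_sites(c.site, nb), ne = 0;
    for (int k = 0; k < nn; ++k) if (occ[nb[k]] < 0) emp[ne++] = nb[k];
    if (ne == 0) {
      schedule(id, t); c_quiesc += 1;
      return OUT_QUIESCENT;
    }
    int target = emp[rand_int(0, ne - 1)];
    if (unif_rand() < p_s) {
      int did = new_cell(target, (uint8_t)(H_EA | H_EI), 1, tl0, 0, m0);
      schedule(did, t);
      c_sym += 1; it_sym += 1;
    } else {
      uint8_t f = (uint8_t)(1 << rand_int(0, 4));
      int did = new_cell(target, f, 0, tl0, 0, m0);
      if (csc_daughter_mut) mutate(did, mut_prob(f, m0), (f & H_GI) != 0);
      schedule(did, t);
      c_asym += 1; it_asym += 1;
    }
    schedule(id, t);  // the CSC itself is unchanged and requeued
    c_div += 1; it_div += 1;
    return OUT_DIVIDED;
  }

  // pop and process one event; fills out_cell/out_time
  int step(int& out_cell, int& out_time) {
    if (pq.empty()) { out_cell = -1; out_time = -1; return OUT_EMPTY_QUEUE; }
    Event ev = pq.top(); pq.pop();
    out_cell = ev.cell; out_time = ev.time;
    Cell& c = cells[ev.cell];
    if (c.site < 0) { ev_stale += 1; return OUT_STALE; }
    if (ev.time < last_time) order_ok = false; else last_time = ev.time;
    ev_live += 1;
    int t = ev.time;
    if (c.csc) return csc_step(ev.cell, t);
    // 1. random cell death test
    if (unif_rand() < 1.0 / a) {
      kill_cell(ev.cell); c_drand += 1; it_drand += 1;
      return OUT_DIED_RANDOM;
    }
    // 2. genetic damage test (skipped when EA is ON)
    int n = 0;
    for (int b = 0; b < 5; ++b) if (c.flags & (1 << b)) ++n;
    if (!(c.flags & H_EA) && n > 0 && unif_rand() < (double)n / e) {
      kill_cell(ev.cell); c_ddam += 1; it_ddam += 1;
      return OUT_DIED_DAMAGE;
    }
    // 3. replicative potential (telomere) check
    if (c.telomere <= 0 && !(c.flags & H_EI)) {
      kill_cell(ev.cell); c_dtel += 1; it_dtel += 1;
      return OUT_DIED_TELOMERE;
    }
    // 4. growth-factor check
    if (!in_region(c.site) && !(c.flags & H_SG)) {
      schedule(ev.cell, t); c_quiesc += 1;
      return OUT_QUIESCENT;
    }
    // 5. space / ignore-growth-inhibit check
    int nb[26], emp[26];
    int nn = neighbor_sites(c.site, nb), ne = 0;
    for (int k = 0; k < nn; ++k) if (occ[nb[k]] < 0) emp[ne++] = nb[k];
    if (ne == 0) {
      if (c.flags & H_IGI) return compete(ev.cell, t, nb, nn);
      schedule(ev.cell, t); c_quiesc += 1;
      return OUT_QUIESCENT;
    }
    do_divide(ev.cell, emp[rand_int(0, ne - 1)], t);
    return OUT_DIVIDED;
  }

  // category scan: 0 empty, 1 healthy, 2 DCC, 3 CSC; also DCC hallmark counts
  void scan(int& nh, int& nd, int& nc, int* hall) const {
    nh = nd = nc = 0;
    for (int b = 0; b < 5; ++b) hall[b] = 0;
    for (int s = 0; s < n_sites; ++s) {
      int id = occ[s];
      if (id < 0) continue;
      const Cell& c = cells[id];
      if (c.csc) { ++nc; continue; }
      if (c.flags == 0) { ++nh; continue; }
      ++nd;
      for (int b = 0; b < 5; ++b) if (c.flags & (1 << b)) ++hall[b];
    }
  }

  int apply_treatment(double kill_prob, bool exact) {
    std::vector<int> dccs;
    for (int s = 0; s < n_sites; ++s) {
      int id = occ[s];
      if (id >= 0 && !cells[id].csc && cells[id].flags != 0) dccs.push_back(id);
    }
    int kills = 0;
    if (exact) {
      int k = (int)std::floor(kill_prob * (double)dccs.size());
      // partial Fisher-Yates draw of k distinct victims
      int n = (int)dccs.size();
      for (int i = 0; i < k; ++i) {
        int j = rand_int(i, n - 1);
        std::swap(dccs[i], dccs[j]);
        kill_cell(dccs[i]);
        ++kills;
      }
    } else {
      for (size_t i = 0; i < dccs.size(); ++i)
        if (unif_rand() < kill_prob) { kill_cell(dccs[i]); ++kills; }
    }
    c_kills += kills; it_kills += kills;
    return kills;
  }
};

// ---- treatment plan activity (mirrors the R-level should_apply) ----

struct PlanC {
  int mode;  // 0 none, 1 pulse, 2 continuous, 3 periodic_pulse, 4 periodic_sustained
  int start, end, period, duration;
  double kill_prob, thr_frac;
  bool exact;
};

static PlanC parse_plan(List plan) {
  PlanC p;
  p.mode = as<int>(plan["mode_code"]);
  p.start = as<int>(plan["start"]);
  double endv = as<double>(plan["end"]);
  p.end = (!R_FINITE(endv) || endv > (double)INT_MAX) ? INT_MAX : (int)endv;
  p.period = as<int>(plan["period"]);
  p.duration = as<int>(plan["pulse_duration"]);
  p.kill_prob = as<double>(plan["kill_prob"]);
  p.thr_frac = as<double>(plan["threshold_fraction"]);
  p.exact = as<bool>(plan["exact"]);
  return p;
}

static bool plan_phase_active(const PlanC& p, int t) {
  switch (p.mode) {
  case 1: return t == p.start;
  case 2: return t >= p.start && t <= p.end;
  case 3: return t >= p.start && t <= p.end && (t - p.start) % p.period == 0;
  case 4: return t >= p.start && t <= p.end && (t - p.start) % p.period < p.duration;
  default: return false;
  }
}

// ---------------- exported interface ----------------

// [[Rcpp::export]]
SEXP engine_create(int side, int margin, bool moore, List params) {
  Engine* eng = new Engine(side, margin, moore, params);
  XPtr<Engine> ptr(eng, true);
  return ptr;
}

// [[Rcpp::export]]
void engine_fill_healthy(SEXP xp) {
  XPtr<Engine> eng(xp);
  eng->fill_healthy();
}

// [[Rcpp::export]]
IntegerVector engine_place_cells(SEXP xp, IntegerVector sites, IntegerVector flags,
                                 IntegerVector csc, IntegerVector telomere,
                                 NumericVector mdenom, IntegerVector delay) {
  XPtr<Engine> eng(xp);
  int n = sites.size();
  IntegerVector ids(n);
  for (int i = 0; i < n; ++i) {
    int s = sites[i];
    if (s < 0 || s >= eng->n_sites) stop("site index out of bounds");
    if (eng->occ[s] >= 0) eng->kill_cell(eng->occ[s]);  // silent replacement
    int id = eng->new_cell(s, (uint8_t)flags[i], (uint8_t)csc[i], telomere[i],
                           0, mdenom[i]);
    if (delay[i] >= 0) {
      Event ev; ev.time = eng->completed + delay[i]; ev.cell = id; ev.seq = eng->seq++;
      eng->pq.push(ev);
    } else {
      eng->schedule(id, eng->completed);
    }
    ids[i] = id;
  }
  return ids;
}

// [[Rcpp::export]]
void engine_remove_sites(SEXP xp, IntegerVector sites) {
  XPtr<Engine> eng(xp);
  for (int i = 0; i < sites.size(); ++i) {
    int s = sites[i];
    if (s < 0 || s >= eng->n_sites) stop("site index out of bounds");
    if (eng->occ[s] >= 0) eng->kill_cell(eng->occ[s]);
  }
}

// [[Rcpp::export]]
List engine_step(SEXP xp) {
  XPtr<Engine> eng(xp);
  int cell, time;
  int out = eng->step(cell, time);
  return List::create(_["code"] = out, _["cell"] = cell, _["time"] = time);
}

// [[Rcpp::export]]
void engine_schedule(SEXP xp, int cell_id) {
  XPtr<Engine> eng(xp);
  if (cell_id < 0 || cell_id >= (int)eng->cells.size() || eng->cells[cell_id].site < 0)
    stop("cannot schedule a mitosis for a dead or unknown cell");
  eng->schedule(cell_id, eng->completed);
}

// [[Rcpp::export]]
void engine_divide(SEXP xp, int cell_id, int target_site) {
  XPtr<Engine> eng(xp);
  if (cell_id < 0 || cell_id >= (int)eng->cells.size() || eng->cells[cell_id].site < 0)
    stop("cell is dead or unknown");
  if (target_site < 0 || target_site >= eng->n_sites) stop("site index out of bounds");
  if (eng->occ[target_site] >= 0)
    stop("target site is occupied; division requires an empty site or competition");
  eng->do_divide(cell_id, target_site, eng->completed);
}

// [[Rcpp::export]]
List engine_compete(SEXP xp, int cell_id) {
  XPtr<Engine> eng(xp);
  if (cell_id < 0 || cell_id >= (int)eng->cells.size() || eng->cells[cell_id].site < 0)
    stop("cell is dead or unknown");
  Cell& c = eng->cells[cell_id];
  int nb[26], ne = 0;
  int nn = eng->neighbor_sites(c.site, nb);
  for (int k = 0; k < nn; ++k) if (eng->occ[nb[k]] < 0) ++ne;
  if (ne > 0) stop("competition requires a fully occupied neighborhood");
  int out = eng->compete(cell_id, eng->completed, nb, nn);
  return List::create(_["code"] = out);
}

// [[Rcpp::export]]
List engine_csc_divide(SEXP xp, int cell_id) {
  XPtr<Engine> eng(xp);
  if (cell_id < 0 || cell_id >= (int)eng->cells.size() || eng->cells[cell_id].site < 0)
    stop("cell is dead or unknown");
  if (!eng->cells[cell_id].csc) stop("csc_attempt_division called on a non-CSC cell");
  int out = eng->csc_step(cell_id, eng->completed);
  return List::create(_["code"] = out);
}

// [[Rcpp::export]]
int engine_apply_treatment(SEXP xp, double kill_prob, bool exact) {
  XPtr<Engine> eng(xp);
  return eng->apply_treatment(kill_prob, exact);
}

// [[Rcpp::export]]
DataFrame engine_run(SEXP xp, int n_iter, Nullable<List> plan_) {
  XPtr<Engine> eng(xp);
  bool has_plan = plan_.isNotNull();
  PlanC plan;
  if (has_plan) plan = parse_plan(plan_.get());
  std::vector<int> v_it, v_h, v_d, v_c, v_e;
  std::vector<int> v_sg, v_igi, v_ea, v_ei, v_gi;
  std::vector<int> v_asym, v_sym, v_kill, v_dr, v_dd, v_dt, v_dc;
  v_it.reserve(n_iter);
  int hall[5];
  for (int k = 0; k < n_iter; ++k) {
    int t = eng->completed + 1;
    if (has_plan && plan.mode != 0 && plan_phase_active(plan, t)) {
      int nh, nd, nc;
      eng->scan(nh, nd, nc, hall);
      if ((double)nd >= plan.thr_frac * (double)eng->n_sites - 1e-9)
        eng->apply_treatment(plan.kill_prob, plan.exact);
    }
    while (!eng->pq.empty() && eng->pq.top().time <= t) {
      int cell, time;
      eng->step(cell, time);
    }
    eng->completed = t;
    int nh, nd, nc;
    eng->scan(nh, nd, nc, hall);
    v_it.push_back(t); v_h.push_back(nh); v_d.push_back(nd); v_c.push_back(nc);
    v_e.push_back(eng->n_sites - nh - nd - nc);
    v_sg.push_back(hall[0]); v_igi.push_back(hall[1]); v_ea.push_back(hall[2]);
    v_ei.push_back(hall[3]); v_gi.push_back(hall[4]);
    v_asym.push_back(eng->it_asym); v_sym.push_back(eng->it_sym);
    v_kill.push_back(eng->it_kills);
    v_dr.push_back(eng->it_drand); v_dd.push_back(eng->it_ddam);
    v_dt.push_back(eng->it_dtel); v_dc.push_back(eng->it_dcomp);
    eng->reset_iter_counters();
    if (k % 256 == 0) Rcpp::checkUserInterrupt();
  }
  return DataFrame::create(
    _["iteration"] = v_it, _["n_healthy"] = v_h, _["n_dcc"] = v_d,
    _["n_csc"] = v_c, _["n_empty"] = v_e,
    _["hall_sg"] = v_sg, _["hall_igi"] = v_igi, _["hall_ea"] = v_ea,
    _["hall_ei"] = v_ei, _["hall_gi"] = v_gi,
    _["asymmetric_divisions"] = v_asym, _["symmetric_divisions"] = v_sym,
    _["treatment_kills"] = v_kill,
    _["deaths_random"] = v_dr, _["deaths_damage"] = v_dd,
    _["deaths_telomere"] = v_dt, _["deaths_competition"] = v_dc);
}

// [[Rcpp::export]]
List engine_counts(SEXP xp, bool reset) {
  XPtr<Engine> eng(xp);
  int nh, nd, nc, hall[5];
  eng->scan(nh, nd, nc, hall);
  List out = List::create(
    _["iteration"] = eng->completed,
    _["n_healthy"] = nh, _["n_dcc"] = nd, _["n_csc"] = nc,
    _["n_empty"] = eng->n_sites - nh - nd - nc,
    _["hall_sg"] = hall[0], _["hall_igi"] = hall[1], _["hall_ea"] = hall[2],
    _["hall_ei"] = hall[3], _["hall_gi"] = hall[4],
    _["asymmetric_divisions"] = eng->it_asym,
    _["symmetric_divisions"] = eng->it_sym,
    _["treatment_kills"] = eng->it_kills,
    _["deaths_random"] = eng->it_drand, _["deaths_damage"] = eng->it_ddam,
    _["deaths_telomere"] = eng->it_dtel, _["deaths_competition"] = eng->it_dcomp);
  if (reset) eng->reset_iter_counters();
  return out;
}

// [[Rcpp::export]]
DataFrame engine_cells(SEXP xp) {
  XPtr<Engine> eng(xp);
  std::vector<int> id, x, y, z, tel, ndiv;
  std::vector<int> sg, igi, ea, ei, gi, csc;
  std::vector<double> mdenom;
  for (size_t i = 0; i < eng->cells.size(); ++i) {
    const Cell& c = eng->cells[i];
    if (c.site < 0) continue;
    int cx, cy, cz; eng->decode(c.site, cx, cy, cz);
    id.push_back((int)i); x.push_back(cx); y.push_back(cy); z.push_back(cz);
    sg.push_back((c.flags & H_SG) != 0); igi.push_back((c.flags & H_IGI) != 0);
    ea.push_back((c.flags & H_EA) != 0); ei.push_back((c.flags & H_EI) != 0);
    gi.push_back((c.flags & H_GI) != 0);
    csc.push_back(c.csc); tel.push_back(c.telomere); ndiv.push_back(c.ndiv);
    mdenom.push_back(c.mdenom);
  }
  return DataFrame::create(
    _["id"] = id, _["x"] = x, _["y"] = y, _["z"] = z,
    _["sg"] = sg, _["igi"] = igi, _["ea"] = ea, _["ei"] = ei, _["gi"] = gi,
    _["is_csc"] = csc, _["telomere"] = tel, _["divisions"] = ndiv,
    _["mutation_denominator"] = mdenom);
}

// [[Rcpp::export]]
IntegerVector engine_occupancy(SEXP xp) {
  XPtr<Engine> eng(xp);
  IntegerVector out(eng->n_sites);
  for (int s = 0; s < eng->n_sites; ++s) {
    int id = eng->occ[s];
    if (id < 0) { out[s] = 0; continue; }
    const Cell& c = eng->cells[id];
    out[s] = c.csc ? 3 : (c.flags == 0 ? 1 : 2);
  }
  return out;
}

// [[Rcpp::export]]
List engine_stats(SEXP xp) {
  XPtr<Engine> eng(xp);
  return List::create(
    _["events_live"] = eng->ev_live, _["events_stale"] = eng->ev_stale,
    _["died_random"] = eng->c_drand, _["died_damage"] = eng->c_ddam,
    _["died_telomere"] = eng->c_dtel, _["died_competition"] = eng->c_dcomp,
    _["divisions"] = eng->c_div, _["quiescent"] = eng->c_quiesc,
    _["competition_attempts"] = eng->comp_att,
    _["competition_successes"] = eng->comp_succ,
    _["mutation_opportunities_base"] = eng->mut_opp_base,
    _["mutation_flips_base"] = eng->mut_flip_base,
    _["mutation_opportunities_gi"] = eng->mut_opp_gi,
    _["mutation_flips_gi"] = eng->mut_flip_gi,
    _["symmetric_divisions"] = eng->c_sym,
    _["asymmetric_divisions"] = eng->c_asym,
    _["treatment_kills"] = eng->c_kills,
    _["event_order_ok"] = eng->order_ok,
    _["last_event_time"] = eng->last_time);
}

// [[Rcpp::export]]
bool engine_validate(SEXP xp) {
  XPtr<Engine> eng(xp);
  int occupied = 0;
  for (int s = 0; s < eng->n_sites; ++s) {
    int id = eng->occ[s];
    if (id < 0) continue;
    ++occupied;
    if (id >= (int)eng->cells.size() || eng->cells[id].site != s)
      stop("occupancy registry inconsistent at site %d", s);
  }
  int alive = 0;
  for (size_t i = 0; i < eng->cells.size(); ++i) {
    const Cell& c = eng->cells[i];
    if (c.site < 0) continue;
    ++alive;
    if (eng->occ[c.site] != (int)i)
      stop("cell %d not registered at its site", (int)i);
    if (c.csc && !((c.flags & H_EA) && (c.flags & H_EI)))
      stop("CSC %d lacks EA/EI flags", (int)i);
  }
  if (alive != occupied) stop("alive cells != occupied sites");
  return true;
}

// [[Rcpp::export]]
int engine_queue_size(SEXP xp) {
  XPtr<Engine> eng(xp);
  return (int)eng->pq.size();
}

// [[Rcpp::export]]
int engine_completed(SEXP xp) {
  XPtr<Engine> eng(xp);
  return eng->completed;
}

// [[Rcpp::export]]
List engine_queue_times(SEXP xp) {
  // drains and restores the queue; for tests only (small queues)
  XPtr<Engine> eng(xp);
  std::vector<Event> evs;
  while (!eng->pq.empty()) { evs.push_back(eng->pq.top()); eng->pq.pop(); }
  IntegerVector times(evs.size()), cells_(evs.size());
  for (size_t i = 0; i < evs.size(); ++i) {
    times[i] = evs[i].time; cells_[i] = evs[i].cell;
    eng->pq.push(evs[i]);
  }
  return List::create(_["time"] = times, _["cell"] = cells_);
}

// [[Rcpp::export]]
void engine_set_option(SEXP xp, std::string name, SEXP value) {
  XPtr<Engine> eng(xp);
  if (name == "p_s") eng->p_s = as<double>(value);
  else if (name == "a") eng->a = as<double>(value);
  else if (name == "e") eng->e = as<double>(value);
  else if (name == "g") eng->g = as<double>(value);
  else if (name == "gi_factor") eng->gi_factor = as<double>(value);
  else if (name == "csc_exempt_random_death") eng->csc_exempt_random = as<bool>(value);
  else if (name == "csc_protected_from_competition") eng->csc_protected = as<bool>(value);
  else if (name == "csc_daughter_mutations") eng->csc_daughter_mut = as<bool>(value);
  else if (name == "igi_failure_kills") eng->igi_failure_kills = as<bool>(value);
  else stop("unknown engine option '%s'", name.c_str());
}

// neighbor helper shared with the R lattice layer (same geometry code path)
// [[Rcpp::export]]
IntegerVector cpp_neighbor_sites(int side, int site, bool moore) {
  if (site < 0 || site >= side * side * side) stop("site index out of bounds");
  int x = site % side, y = (site / side) % side, z = site / (side * side);
  std::vector<int> out;
  for (int dz = -1; dz <= 1; ++dz)
    for (int dy = -1; dy <= 1; ++dy)
      for (int dx = -1; dx <= 1; ++dx) {
        if (dx == 0 && dy == 0 && dz == 0) continue;
        if (!moore && (std::abs(dx) + std::abs(dy) + std::abs(dz) != 1)) continue;
        int nx = x + dx, ny = y + dy, nz = z + dz;
        if (nx < 0 || nx >= side || ny < 0 || ny >= side || nz < 0 || nz >= side)
          continue;
        out.push_back(nx + side * (ny + side * nz));
      }
  return wrap(out);
}
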