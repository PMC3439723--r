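// Reachability analysis and event-level simulation for compiled
// process-algebra models.
//
// A compiled model consists of component types (local states with their
// enabled prefixes), a vector of sequential instances, and a binary
// cooperation tree whose leaves are instances.  A global state is the
// tuple of local states, one per instance.  A shared action in a
// cooperation proceeds at the minimum of the operands' apparent rates,
// split across the enabled source combinations in proportion to their
// contribution (the standard minimum-based cooperation rule).

#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <string>
#include <queue>
#include <cstdint>

using namespace Rcpp;

namespace {

struct Prefix { int action; double rate; int target; };

struct CompType {
  // prefixes grouped by local state
  std::vector<std::vector<Prefix>> locals;
};

struct Node {
  int kind;              // 0 = leaf, 1 = cooperation
  int a, b;              // leaf: a = instance index; coop: child node indices
  std::vector<int> sync; // action ids (cooperation only)
};

struct Model {
  std::vector<CompType> types;
  std::vector<int> inst_type, inst_init;
  std::vector<Node> nodes;
  int root;
  int n_actions;
};

struct Tr {
  int action;
  double rate;
  std::vector<std::pair<int,int>> upd; // (instance, new local)
};

Model build_model(const List& compiled) {
  Model m;
  List types = compiled["types"];
  for (R_xlen_t t = 0; t < types.size(); ++t) {
    List ty = types[t];
    List pa = ty["prefix_action"], pr = ty["prefix_rate"], pt = ty["prefix_target"];
    CompType ct;
    for (R_xlen_t s = 0; s < pa.size(); ++s) {
      IntegerVector act = pa[s], tgt = pt[s];
      NumericVector rate = pr[s];
      std::vector<Prefix> v(act.size());
      for (int k = 0; k < act.size(); ++k) v[k] = Prefix{act[k], rate[k], tgt[k]};
      ct.locals.push_back(std::move(v));
    }
    m.types.push_back(std::move(ct));
  }
  IntegerMatrix inst = compiled["instances"];
  for (int i = 0; i < inst.nrow(); ++i) {
    m.inst_type.push_back(inst(i, 0));
    m.inst_init.push_back(inst(i, 1));
  }
  List nodes = compiled["tree"];
  for (R_xlen_t i = 0; i < nodes.size(); ++i) {
    List nd = nodes[i];
    Node n;
    n.kind = as<int>(nd["kind"]);
    n.a = as<int>(nd["a"]);
    n.b = as<int>(nd["b"]);
    IntegerVector sy = nd["sync"];
    n.sync.assign(sy.begin(), sy.end());
    m.nodes.push_back(std::move(n));
  }
  m.root = as<int>(compiled["root"]);
  m.n_actions = as<int>(compiled["n_actions"]);
  return m;
}

void collect(const Model& m, int node_id, const std::vector<uint8_t>& st,
             std::vector<Tr>& out) {
  const Node& nd = m.nodes[node_id];
  if (nd.kind == 0) {
    int inst = nd.a;
    const CompType& ty = m.types[m.inst_type[inst]];
    const std::vector<Prefix>& pf = ty.locals[st[inst]];
    for (const Prefix& p : pf) {
      Tr t;
      t.action = p.action;
      t.rate = p.rate;
      t.upd.push_back({inst, p.target});
      out.push_back(std::move(t));
    }
    return;
  }
  std::vector<Tr> lt, rt;
  collect(m, nd.a, st, lt);
  collect(m, nd.b, st, rt);
  if (nd.sync.empty()) {
    for (auto& t : lt) out.push_back(std::move(t));
    for (auto& t : rt) out.push_back(std::move(t));
    return;
  }
  std::vector<char> is_sync(m.n_actions, 0);
  for (int a : nd.sync) is_sync[a] = 1;
  // pass through non-shared actions
  for (auto& t : lt) if (!is_sync[t.action]) out.push_back(t);
  for (auto& t : rt) if (!is_sync[t.action]) out.push_back(t);
  // combine shared actions at min of apparent rates
  for (int a : nd.sync) {
    double appL = 0, appR = 0;
    for (const auto& t : lt) if (t.action == a) appL += t.rate;
    for (const auto& t : rt) if (t.action == a) appR += t.rate;
    if (appL <= 0 || appR <= 0) continue;
    double total = std::min(appL, appR);
    for (const auto& l : lt) {
      if (l.action != a) continue;
      for (const auto& r : rt) {
        if (r.action != a) continue;
        Tr t;
        t.action = a;
        t.rate = (l.rate / appL) * (r.rate / appR) * total;
        t.upd = l.upd;
        t.upd.insert(t.upd.end(), r.upd.begin(), r.upd.end());
        out.push_back(std::move(t));
      }
    }
  }
}

std::string key_of(const std::vector<uint8_t>& st) {
  return std::string(st.begin(), st.end());
}

} // namespace

// [[Rcpp::export(name = ".explore_cpp")]]
List explore_cpp(List compiled, double max_states) {
  Model m = build_model(compiled);
  const int n_inst = (int)m.inst_type.size();

  std::vector<uint8_t> init(n_inst);
  for (int i = 0; i < n_inst; ++i) init[i] = (uint8_t)m.inst_init[i];

  std::unordered_map<std::string, int> index;
  std::vector<std::vector<uint8_t>> states;
  std::queue<int> frontier;

  index[key_of(init)] = 0;
  states.push_back(init);
  frontier.push(0);

  std::vector<int> e_src, e_tgt, e_act;
  std::vector<double> e_rate;

  std::vector<Tr> trs;
  while (!frontier.empty()) {
    int si = frontier.front(); frontier.pop();
    const std::vector<uint8_t> st = states[si];
    trs.clear();
    collect(m, m.root, st, trs);
    for (const Tr& t : trs) {
      std::vector<uint8_t> ns = st;
      for (auto& u : t.upd) ns[u.first] = (uint8_t)u.second;
      std::string k = key_of(ns);
      auto it = index.find(k);
      int ti;
      if (it == index.end()) {
        ti = (int)states.size();
        if ((double)(ti + 1) > max_states)
          stop("state budget exceeded: more than %g reachable states", max_states);
        index[k] = ti;
        states.push_back(ns);
        frontier.push(ti);
      } else ti = it->second;
      e_src.push_back(si + 1);
      e_tgt.push_back(ti + 1);
      e_act.push_back(t.action + 1);
      e_rate.push_back(t.rate);
    }
    if ((states.size() & 0x3FF) == 0) Rcpp::checkUserInterrupt();
  }

  const int n = (int)states.size();
  IntegerMatrix sm(n, n_inst);
  for (int i = 0; i < n; ++i)
    for (int j = 0; j < n_inst; ++j) sm(i, j) = states[i][j] + 1;

  return List::create(
    _["states"] = sm,
    _["src"] = wrap(e_src),
    _["tgt"] = wrap(e_tgt),
    _["action"] = wrap(e_act),
    _["rate"] = wrap(e_rate));
}

// Gillespie simulation on an explored transition system.  Uses R's RNG so
// that runs are reproducible under set.seed().  Returns time-weighted
// state occupancy, the number of firings per action, and the final state.
// [[Rcpp::export(name = ".simulate_ts_cpp")]]
List simulate_ts_cpp(int n_states, IntegerVector src, IntegerVector tgt,
                     IntegerVector action, NumericVector rate,
                     int n_actions, int init, double n_events) {
  // CSR-style grouping of edges by source
  std::vector<int> count(n_states, 0);
  for (int e = 0; e < src.size(); ++e) count[src[e] - 1]++;
  std::vector<int> start(n_states + 1, 0);
  for (int s = 0; s < n_states; ++s) start[s + 1] = start[s] + count[s];
  std::vector<int> pos(start.begin(), start.end() - 1);
  std::vector<int> etgt(src.size()), eact(src.size());
  std::vector<double> erate(src.size());
  for (int e = 0; e < src.size(); ++e) {
    int s = src[e] - 1, p = pos[s]++;
    etgt[p] = tgt[e] - 1;
    eact[p] = action[e] - 1;
    erate[p] = rate[e];
  }
  std::vector<double> total(n_states, 0.0);
  for (int s = 0; s < n_states; ++s)
    for (int p = start[s]; p < start[s + 1]; ++p) total[s] += erate[p];

  NumericVector occupancy(n_states);
  NumericVector firings(n_actions);
  GetRNGstate();
  int cur = init - 1;
  for (double ev = 0; ev < n_events; ++ev) {
    double r = total[cur];
    if (r <= 0) stop("absorbing state reached during simulation");
    occupancy[cur] += ::Rf_rexp(1.0 / r);
    double u = ::unif_rand() * r, acc = 0;
    int chosen = start[cur + 1] - 1;
    for (int p = start[cur]; p < start[cur + 1]; ++p) {
      acc += erate[p];
      if (u <= acc) { chosen = p; break; }
    }
    firings[eact[chosen]] += 1.0;
    cur = etgt[chosen];
  }
  PutRNGstate();
  return List::create(_["occupancy"] = occupancy, _["firings"] = firings,
                      _["final_state"] = cur + 1);
}

// ---- fluid right-hand side -------------------------------------------------
//
// The mean-field drift evaluation is performance-critical (it is called by
// the stiff integrator many thousands of times per solve), so the coupling
// structure is compiled once into a C++ object held by an external pointer.

namespace {

struct FluidPrefix { int src, action, tgt; double rate; };

struct FluidSys {
  int n_vars, n_act, root;
  // per leaf (group): its prefixes
  std::vector<std::vector<FluidPrefix>> leaf_pref;
  // tree
  std::vector<int> kind, a, b;           // kind 0 leaf (a = leaf index), 1 coop
  std::vector<std::vector<char>> sync;   // per node: action membership
  // workspace
  std::vector<double> app;               // n_nodes * n_act
};

void fluid_alloc(FluidSys& f, int ni, int act, double total,
                 const double* N, double* dN) {
  if (total <= 0) return;
  if (f.kind[ni] == 0) {
    double ag = f.app[ni * f.n_act + act];
    if (ag <= 0) return;
    for (const FluidPrefix& p : f.leaf_pref[f.a[ni]]) {
      if (p.action != act) continue;
      double fl = total * p.rate * N[p.src] / ag;
      dN[p.src] -= fl;
      dN[p.tgt] += fl;
    }
    return;
  }
  if (f.sync[ni][act]) {
    fluid_alloc(f, f.a[ni], act, total, N, dN);
    fluid_alloc(f, f.b[ni], act, total, N, dN);
  } else {
    double al = f.app[f.a[ni] * f.n_act + act];
    double ar = f.app[f.b[ni] * f.n_act + act];
    if (al + ar > 0) {
      fluid_alloc(f, f.a[ni], act, total * al / (al + ar), N, dN);
      fluid_alloc(f, f.b[ni], act, total * ar / (al + ar), N, dN);
    }
  }
}

} // namespace

// [[Rcpp::export(name = ".fluid_compile_cpp")]]
SEXP fluid_compile_cpp(List spec) {
  XPtr<FluidSys> p(new FluidSys, true);
  p->n_vars = as<int>(spec["n_vars"]);
  p->n_act = as<int>(spec["n_actions"]);
  p->root = as<int>(spec["root"]) - 1;
  List lp = spec["leaf_pref"];
  for (R_xlen_t i = 0; i < lp.size(); ++i) {
    List one = lp[i];
    IntegerVector src = one["src"], act = one["action"], tgt = one["tgt"];
    NumericVector rate = one["rate"];
    std::vector<FluidPrefix> v(src.size());
    for (int k = 0; k < src.size(); ++k)
      v[k] = FluidPrefix{src[k] - 1, act[k] - 1, tgt[k] - 1, rate[k]};
    p->leaf_pref.push_back(std::move(v));
  }
  List nodes = spec["nodes"];
  for (R_xlen_t i = 0; i < nodes.size(); ++i) {
    List nd = nodes[i];
    bool leaf = as<std::string>(nd["kind"]) == "leaf";
    p->kind.push_back(leaf ? 0 : 1);
    p->a.push_back(as<int>(nd["a"]) - 1);
    p->b.push_back(leaf ? -1 : as<int>(nd["b"]) - 1);
    std::vector<char> sy(p->n_act, 0);
    if (!leaf) {
      IntegerVector s = nd["sync"];
      for (int k = 0; k < s.size(); ++k) sy[s[k] - 1] = 1;
    }
    p->sync.push_back(std::move(sy));
  }
  p->app.resize(p->kind.size() * p->n_act);
  return p;
}

// [[Rcpp::export(name = ".fluid_rhs_cpp")]]
NumericVector fluid_rhs_cpp(SEXP ptr, NumericVector N) {
  XPtr<FluidSys> p(ptr);
  FluidSys& f = *p;
  const int n_nodes = (int)f.kind.size(), na = f.n_act;
  // bottom-up apparent rates (nodes are created children-first)
  for (int ni = 0; ni < n_nodes; ++ni) {
    double* row = &f.app[ni * na];
    if (f.kind[ni] == 0) {
      std::fill(row, row + na, 0.0);
      for (const FluidPrefix& pf : f.leaf_pref[f.a[ni]])
        row[pf.action] += pf.rate * N[pf.src];
    } else {
      const double* l = &f.app[f.a[ni] * na];
      const double* r = &f.app[f.b[ni] * na];
      for (int ac = 0; ac < na; ++ac)
        row[ac] = f.sync[ni][ac] ? std::min(l[ac], r[ac]) : l[ac] + r[ac];
    }
  }
  NumericVector dN(f.n_vars);
  for (int ac = 0; ac < na; ++ac)
    fluid_alloc(f, f.root, ac, f.app[f.root * na + ac], N.begin(), dN.begin());
  return dN;
}

// [[Rcpp::export(name = ".ptr_valid_cpp")]]
bool ptr_valid_cpp(SEXP ptr) {
  return TYPEOF(ptr) == EXTPTRSXP && R_ExternalPtrAddr(ptr) != NULL;
}
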