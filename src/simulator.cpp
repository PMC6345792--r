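// Exact event-driven simulation of stochastic reaction kinetics in growing,
// dividing cell populations. Chemistry within a cell is simulated with the
// direct stochastic simulation algorithm; division times are drawn at birth
// from the interdivision-time law (equivalent to the age-dependent hazard);
// molecules are partitioned binomially between daughters. Cells evolve
// independently given the division schedule, so each cell's chemistry is
// advanced lazily (at its division, or at the final snapshot).

#include <Rcpp.h>
#include <queue>
#include <vector>
using namespace Rcpp;

namespace {

struct Net {
  int n, R;
  IntegerMatrix nu, order;
  IntegerVector type, hill_s, burst_s;
  NumericVector rate, hillK, hilln, burst_b;
  explicit Net(const List& l)
      : n(as<int>(l["n"])), R(as<int>(l["R"])),
        nu(as<IntegerMatrix>(l["nu"])), order(as<IntegerMatrix>(l["order"])),
        type(as<IntegerVector>(l["type"])),
        hill_s(as<IntegerVector>(l["hill_s"])),
        burst_s(as<IntegerVector>(l["burst_s"])),
        rate(as<NumericVector>(l["rate"])),
        hillK(as<NumericVector>(l["hillK"])),
        hilln(as<NumericVector>(l["hilln"])),
        burst_b(as<NumericVector>(l["burst_b"])) {}
};

double propensity(const Net& net, int r, const std::vector<int>& x) {
  switch (net.type[r]) {
    case 0: { // mass action, falling factorials on integer counts
      double w = net.rate[r];
      for (int i = 0; i < net.n; ++i) {
        int k = net.order(i, r);
        for (int j = 0; j < k; ++j) w *= (x[i] - j > 0) ? (x[i] - j) : 0;
      }
      return w;
    }
    case 1: { // Hill repression
      double p = x[net.hill_s[r]];
      return net.rate[r] / (1.0 + std::pow(p / net.hillK[r], net.hilln[r]));
    }
    default: // burst production fires at its base rate
      return net.rate[r];
  }
}

// Advance one cell's chemistry for `duration` time units (in place).
void ssa(const Net& net, std::vector<int>& x, double duration) {
  if (duration <= 0) return;
  double t = 0;
  std::vector<double> w(net.R);
  for (;;) {
    double a0 = 0;
    for (int r = 0; r < net.R; ++r) { w[r] = propensity(net, r, x); a0 += w[r]; }
    if (a0 <= 0) return;
    t += R::exp_rand() / a0;
    if (t > duration) return;
    double u = unif_rand() * a0;
    int r = 0;
    for (; r < net.R - 1; ++r) { u -= w[r]; if (u <= 0) break; }
    if (net.type[r] == 2) {
      // geometric burst on {0,1,...} with mean b
      double b = net.burst_b[r];
      x[net.burst_s[r]] += (int)R::rgeom(1.0 / (1.0 + b));
    } else {
      for (int i = 0; i < net.n; ++i) x[i] += net.nu(i, r);
    }
  }
}

// Interdivision time draw: family 0 exp, 1 gamma, 2 lognormal, 3 deterministic
double draw_tau(int family, double p1, double p2) {
  switch (family) {
    case 0: return R::rexp(p1);           // p1 = mean
    case 1: return R::rgamma(p1, p2);     // shape, scale
    case 2: return R::rlnorm(p1, p2);     // meanlog, sdlog
    default: return p1;                   // deterministic T
  }
}

struct Cell {
  double birth, div;
  int depth;
  bool alive;
  std::vector<int> x;
};

} // namespace

// [[Rcpp::export]]
IntegerVector ssa_cpp(List net_spec, IntegerVector x0, double duration) {
  Net net(net_spec);
  std::vector<int> x(x0.begin(), x0.end());
  ssa(net, x, duration);
  return IntegerVector(x.begin(), x.end());
}

// [[Rcpp::export]]
List simulate_population_cpp(List net_spec, int family, double p1, double p2,
                             IntegerVector x0, double t_final, int n_max,
                             int max_cells) {
  Net net(net_spec);
  std::vector<Cell> cells;
  typedef std::pair<double, int> Ev;
  std::priority_queue<Ev, std::vector<Ev>, std::greater<Ev> > heap;
  std::vector<int> alive_idx;          // indices of live cells
  std::vector<int> pos;                // cell index -> position in alive_idx

  Cell root;
  root.birth = 0; root.depth = 0; root.alive = true;
  root.x.assign(x0.begin(), x0.end());
  root.div = draw_tau(family, p1, p2);
  cells.push_back(root);
  pos.push_back(0);
  alive_idx.push_back(0);
  heap.push(Ev(root.div, 0));

  std::vector<double> growth_t;
  std::vector<int> growth_n;
  double t_snap = t_final;

  auto kill = [&](int idx) {
    cells[idx].alive = false;
    int p = pos[idx];
    int last = alive_idx.back();
    alive_idx[p] = last;
    pos[last] = p;
    alive_idx.pop_back();
  };

  while (!heap.empty()) {
    Ev ev = heap.top();
    int i = ev.second;
    if (!cells[i].alive) { heap.pop(); continue; }
    if (ev.first > t_final) break;
    heap.pop();
    double t = ev.first;

    // advance mother chemistry to division, then split binomially
    std::vector<int> xm = cells[i].x;
    ssa(net, xm, cells[i].div - cells[i].birth);
    Cell d1, d2;
    d1.birth = d2.birth = t;
    d1.depth = d2.depth = cells[i].depth + 1;
    d1.alive = d2.alive = true;
    d1.x.resize(net.n); d2.x.resize(net.n);
    for (int s = 0; s < net.n; ++s) {
      int k = (int)R::rbinom((double)xm[s], 0.5);
      d1.x[s] = k;
      d2.x[s] = xm[s] - k;
    }
    d1.div = t + draw_tau(family, p1, p2);
    d2.div = t + draw_tau(family, p1, p2);
    kill(i);
    for (int c = 0; c < 2; ++c) {
      cells.push_back(c == 0 ? d1 : d2);
      int idx = (int)cells.size() - 1;
      pos.push_back((int)alive_idx.size());
      alive_idx.push_back(idx);
      heap.push(Ev(cells[idx].div, idx));
    }
    growth_t.push_back(t);
    growth_n.push_back((int)alive_idx.size());

    // chemostat mode: random removal of excess cells
    if (n_max > 0) {
      while ((int)alive_idx.size() > n_max) {
        int v = (int)std::floor(unif_rand() * alive_idx.size());
        if (v == (int)alive_idx.size()) --v;
        kill(alive_idx[v]);
      }
    }
    if (max_cells > 0 && (int)alive_idx.size() >= max_cells) {
      t_snap = t;
      break;
    }
    if ((int)cells.size() > 40000000)
      stop("tree too large; use constant-N (chemostat) mode");
  }

  int nl = (int)alive_idx.size();
  NumericVector age(nl);
  IntegerVector depth(nl);
  IntegerMatrix counts(nl, net.n);
  for (int k = 0; k < nl; ++k) {
    Cell& c = cells[alive_idx[k]];
    double a = t_snap - c.birth;
    std::vector<int> x = c.x;
    ssa(net, x, a);
    age[k] = a;
    depth[k] = c.depth;
    for (int s = 0; s < net.n; ++s) counts(k, s) = x[s];
  }
  return List::create(_["age"] = age, _["depth"] = depth,
                      _["counts"] = counts, _["time"] = t_snap,
                      _["growth_t"] = growth_t, _["growth_n"] = growth_n);
}

// [[Rcpp::export]]
List simulate_lineage_cpp(List net_spec, int family, double p1, double p2,
                          IntegerVector x0, int n_divisions, double dt) {
  Net net(net_spec);
  std::vector<int> x(x0.begin(), x0.end());
  std::vector<double> s_time, s_age;
  std::vector<std::vector<int> > s_x;
  std::vector<double> div_times;
  double t = 0, t_birth = 0, next_sample = dt;

  for (int d = 0; d < n_divisions; ++d) {
    double tau_d = draw_tau(family, p1, p2);
    double t_div = t_birth + tau_d;
    while (next_sample <= t_div) {
      ssa(net, x, next_sample - t);
      t = next_sample;
      s_time.push_back(t);
      s_age.push_back(t - t_birth);
      s_x.push_back(x);
      next_sample += dt;
    }
    ssa(net, x, t_div - t);
    t = t_div;
    // keep one daughter at random; with symmetric binomial partitioning the
    // kept daughter's counts are Binomial(x, 1/2) either way
    for (int s = 0; s < net.n; ++s)
      x[s] = (int)R::rbinom((double)x[s], 0.5);
    div_times.push_back(t_div);
    t_birth = t_div;
  }

  int m = (int)s_time.size();
  IntegerMatrix counts(m, net.n);
  for (int k = 0; k < m; ++k)
    for (int s = 0; s < net.n; ++s) counts(k, s) = s_x[k][s];
  return List::create(_["time"] = NumericVector(s_time.begin(), s_time.end()),
                      _["age"] = NumericVector(s_age.begin(), s_age.end()),
                      _["counts"] = counts,
                      _["division_times"] =
                          NumericVector(div_times.begin(), div_times.end()));
}
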