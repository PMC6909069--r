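// Compiled core of the Farmer's Game.
//
// Semantics mirror the pure-R reference path (run_round) exactly,
// including random-stream usage: the only draws are one unif_rand() per
// tit-for-tat retaliation decision, taken lower-id player first within an
// interaction, so seeded runs agree bit-for-bit between engines.

#include <Rcpp.h>
#include <set>
#include <unordered_map>
#include <vector>

using namespace Rcpp;

namespace {

const int S_TITFORTAT = 1, S_SUBSIST = 2, S_EXPLOIT = 3, S_THIEF = 4,
          S_MIDDLE = 5, S_DEFECT = 6;
const char MV_C = 1, MV_D = 2;

struct Engine {
  int n;
  std::vector<std::set<int> > adj;   // 0-based node ids
  std::vector<char> alive;
  std::vector<double> wealth;
  std::vector<int> strat, cls;       // strategy 1..6, class 1 poor / 2 rich
  std::vector<std::unordered_map<int, char> > memory;
  double reward, temptation, sucker, punish;
  double turn_cost, forgiveness, subsist_thr, middle_thr, ratio_trig;
  bool reconnect_pair;

  char decide(int i, int j) {
    bool trigger = false;
    switch (strat[i]) {
    case S_DEFECT:  trigger = true; break;
    case S_SUBSIST: trigger = wealth[i] <= subsist_thr; break;
    case S_MIDDLE:  trigger = wealth[i] <= middle_thr; break;
    case S_EXPLOIT: trigger = wealth[i] >= ratio_trig * wealth[j]; break;
    case S_THIEF:   trigger = wealth[j] >= ratio_trig * wealth[i]; break;
    default: break;
    }
    if (trigger) return MV_D;
    std::unordered_map<int, char>::iterator it = memory[i].find(j);
    if (it == memory[i].end() || it->second == MV_C) return MV_C;
    return (unif_rand() < forgiveness) ? MV_C : MV_D;
  }

  double gross(char mine, char theirs) {
    if (mine == MV_C) return theirs == MV_C ? reward : sucker;
    return theirs == MV_C ? temptation : punish;
  }

  // Simultaneous removal: mark all dying dead first, then connect each
  // one's still-alive former neighbours pairwise (skipping existing edges).
  void kill(const std::vector<int> &dying) {
    std::vector<std::vector<int> > former(dying.size());
    for (size_t k = 0; k < dying.size(); ++k) {
      former[k].assign(adj[dying[k]].begin(), adj[dying[k]].end());
      alive[dying[k]] = 0;
    }
    for (size_t k = 0; k < dying.size(); ++k) {
      int nd = dying[k];
      for (size_t m = 0; m < former[k].size(); ++m)
        adj[former[k][m]].erase(nd);
      adj[nd].clear();
    }
    for (size_t k = 0; k < dying.size(); ++k) {
      std::vector<int> live;
      for (size_t m = 0; m < former[k].size(); ++m)
        if (alive[former[k][m]]) live.push_back(former[k][m]);
      if (reconnect_pair) {
        // nested pairing of the ascending neighbour list: opposite
        // neighbours on the intact lattice; degree-preserving
        size_t m = live.size();
        for (size_t a = 0; a < m / 2; ++a) {
          adj[live[a]].insert(live[m - 1 - a]);
          adj[live[m - 1 - a]].insert(live[a]);
        }
      } else {
        for (size_t a = 0; a + 1 < live.size(); ++a)
          for (size_t b = a + 1; b < live.size(); ++b) {
            adj[live[a]].insert(live[b]);
            adj[live[b]].insert(live[a]);
          }
      }
    }
  }
};

}  // namespace

// [[Rcpp::export(name = ".fg_run_engine")]]
List fg_run_engine(int rows, int cols, bool borderless,
                   IntegerVector strategy, IntegerVector cls,
                   NumericVector wealth0,
                   double reward_cc, double temptation_dc, double sucker_cd,
                   double punish_dd, double turn_cost, double forgiveness,
                   double subsist_thr, double middle_thr, double ratio_trig,
                   int rounds, bool reconnect_pair) {
  Engine e;
  e.n = rows * cols;
  e.adj.resize(e.n);
  e.alive.assign(e.n, 1);
  e.wealth.assign(wealth0.begin(), wealth0.end());
  e.strat.assign(strategy.begin(), strategy.end());
  e.cls.assign(cls.begin(), cls.end());
  e.memory.resize(e.n);
  e.reward = reward_cc; e.temptation = temptation_dc;
  e.sucker = sucker_cd; e.punish = punish_dd;
  e.turn_cost = turn_cost; e.forgiveness = forgiveness;
  e.subsist_thr = subsist_thr; e.middle_thr = middle_thr;
  e.ratio_trig = ratio_trig;
  e.reconnect_pair = reconnect_pair;

  for (int r = 0; r < rows; ++r)
    for (int c = 0; c < cols; ++c) {
      int i = r * cols + c;
      if (borderless) {
        e.adj[i].insert(((r - 1 + rows) % rows) * cols + c);
        e.adj[i].insert(((r + 1) % rows) * cols + c);
        e.adj[i].insert(r * cols + (c - 1 + cols) % cols);
        e.adj[i].insert(r * cols + (c + 1) % cols);
      } else {
        if (r > 0) e.adj[i].insert((r - 1) * cols + c);
        if (r < rows - 1) e.adj[i].insert((r + 1) * cols + c);
        if (c > 0) e.adj[i].insert(r * cols + c - 1);
        if (c < cols - 1) e.adj[i].insert(r * cols + c + 1);
      }
    }

  NumericMatrix alive_series(rounds + 1, 12), wealth_series(rounds + 1, 12);
  IntegerVector interactions(rounds), deaths_per_round(rounds);
  NumericVector gross_per_round(rounds);
  IntegerVector death_round(e.n, NA_INTEGER);
  NumericVector death_wealth(e.n, NA_REAL);

  for (int i = 0; i < e.n; ++i) {
    int k = (e.cls[i] - 1) * 6 + e.strat[i] - 1;
    alive_series(0, k) += 1;
    wealth_series(0, k) += e.wealth[i];
  }

  std::vector<int> ea, eb;
  for (int r = 1; r <= rounds; ++r) {
    // snapshot of the live edge list at round start, lexicographic order
    ea.clear(); eb.clear();
    for (int i = 0; i < e.n; ++i) {
      if (!e.alive[i]) continue;
      for (std::set<int>::iterator it = e.adj[i].begin();
           it != e.adj[i].end(); ++it)
        if (*it > i) { ea.push_back(i); eb.push_back(*it); }
    }
    int played = 0, died_now = 0;
    double gross_sum = 0.0;
    for (size_t k = 0; k < ea.size(); ++k) {
      int a = ea[k], b = eb[k];
      if (!e.alive[a] || !e.alive[b]) continue;
      char ma = e.decide(a, b);
      char mb = e.decide(b, a);
      e.memory[a][b] = mb;
      e.memory[b][a] = ma;
      double ga = e.gross(ma, mb), gb = e.gross(mb, ma);
      e.wealth[a] += ga - e.turn_cost;
      e.wealth[b] += gb - e.turn_cost;
      gross_sum += ga + gb;
      ++played;
      std::vector<int> dying;
      if (e.wealth[a] <= 0) dying.push_back(a);
      if (e.wealth[b] <= 0) dying.push_back(b);
      if (!dying.empty()) {
        e.kill(dying);
        for (size_t m = 0; m < dying.size(); ++m) {
          death_round[dying[m]] = r;
          death_wealth[dying[m]] = e.wealth[dying[m]];
        }
        died_now += (int)dying.size();
      }
    }
    interactions[r - 1] = played;
    gross_per_round[r - 1] = gross_sum;
    deaths_per_round[r - 1] = died_now;
    for (int i = 0; i < e.n; ++i) {
      if (!e.alive[i]) continue;
      int k = (e.cls[i] - 1) * 6 + e.strat[i] - 1;
      alive_series(r, k) += 1;
      wealth_series(r, k) += e.wealth[i];
    }
  }

  LogicalVector alive_out(e.n);
  NumericVector wealth_out(e.n);
  for (int i = 0; i < e.n; ++i) {
    alive_out[i] = e.alive[i] != 0;
    wealth_out[i] = e.wealth[i];
  }
  return List::create(
      _["wealth"] = wealth_out, _["alive"] = alive_out,
      _["death_round"] = death_round, _["death_wealth"] = death_wealth,
      _["alive_series"] = alive_series, _["wealth_series"] = wealth_series,
      _["interactions"] = interactions, _["gross"] = gross_per_round,
      _["deaths_per_round"] = deaths_per_round);
}
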