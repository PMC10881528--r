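// On-lattice stochastic tumor microenvironment simulator.
//
// Agents (tumor cells, resistant tumor cells, fibroblasts, M1/M2 macrophages)
// occupy at most one cell of a bounded rectangular grid. Each 4-hour tick the
// agent groups act in the order tumor -> fibroblast -> M1 -> M2; within a
// group the order is reshuffled every tick. All randomness comes from R's RNG
// (unif_rand), so set.seed() on the R side makes runs fully reproducible.
//
// Kind codes (shared with the R side and snapshot CSVs):
//   0 empty, 1 tumor, 2 resistant tumor, 3 fibroblast, 4 M1, 5 M2

#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <climits>
using namespace Rcpp;

namespace {

struct Params {
  double TUpprol, TUpmig, TUpdeath, TUrwalk;
  int    TUpmax;
  double TUpres, TUpprolres, TUpmigres;
  int    TUpmaxres;
  double M1pkill, M1pmig, M1rwalk;
  int    M1kmax, M1speed, M1engagementDuration;
  double M2pkill, M2pmig, M2rwalk;
  int    M2kmax, M2speed, M2engagementDuration;
  double M2TUadd;
  double Fpprol, Fpmig, Fpdeath, Frwalk;
  int    Fpmax;     // -1 = unlimited
  double Mpdeath;
};

Params paramsFromList(const List& p) {
  Params q;
  q.TUpprol   = as<double>(p["TUpprol"]);
  q.TUpmig    = as<double>(p["TUpmig"]);
  q.TUpdeath  = as<double>(p["TUpdeath"]);
  q.TUrwalk   = as<double>(p["TUrwalk"]);
  q.TUpmax    = as<int>(p["TUpmax"]);
  q.TUpres    = as<double>(p["TUpres"]);
  q.TUpprolres = as<double>(p["TUpprolres"]);
  q.TUpmigres = as<double>(p["TUpmigres"]);
  q.TUpmaxres = as<int>(p["TUpmaxres"]);
  q.M1pkill   = as<double>(p["M1pkill"]);
  q.M1pmig    = as<double>(p["M1pmig"]);
  q.M1rwalk   = as<double>(p["M1rwalk"]);
  q.M1kmax    = as<int>(p["M1kmax"]);
  q.M1speed   = as<int>(p["M1speed"]);
  q.M1engagementDuration = as<int>(p["M1engagementDuration"]);
  q.M2pkill   = as<double>(p["M2pkill"]);
  q.M2pmig    = as<double>(p["M2pmig"]);
  q.M2rwalk   = as<double>(p["M2rwalk"]);
  q.M2kmax    = as<int>(p["M2kmax"]);
  q.M2speed   = as<int>(p["M2speed"]);
  q.M2engagementDuration = as<int>(p["M2engagementDuration"]);
  q.M2TUadd   = as<double>(p["M2TUadd"]);
  q.Fpprol    = as<double>(p["Fpprol"]);
  q.Fpmig     = as<double>(p["Fpmig"]);
  q.Fpdeath   = as<double>(p["Fpdeath"]);
  q.Frwalk    = as<double>(p["Frwalk"]);
  q.Fpmax     = as<int>(p["Fpmax"]);
  q.Mpdeath   = as<double>(p["Mpdeath"]);
  return q;
}

inline int runifInt(int n) {           // uniform on 0..n-1
  int k = (int)(unif_rand() * n);
  return (k >= n) ? n - 1 : k;
}

const int EV_BIRTH = 1, EV_DEATH = 2, EV_KILL = 3;

class Sim {
public:
  int W, H, tick;
  Params p;
  std::vector<int> occ;                // W*H, agent index + 1, 0 = empty
  std::vector<int> kind, row, col, divs, kills, engage;
  std::vector<char> alive;
  int cnt[6];                          // live counts per kind code
  bool recordEvents;
  std::vector<int> evTick, evType, evKind, evId, evRow, evCol,
                   evKiller, evKRow, evKCol;

  Sim(int W_, int H_, const Params& p_) : W(W_), H(H_), tick(0), p(p_),
      occ(W_ * H_, 0), recordEvents(false) {
    std::fill(cnt, cnt + 6, 0);
  }

  inline int at(int r, int c) const { return occ[r * W + c]; }

  void loadAgents(const IntegerVector& k, const IntegerVector& r,
                  const IntegerVector& c, const IntegerVector& d,
                  const IntegerVector& kl, const IntegerVector& en,
                  const LogicalVector& al) {
    int n = k.size();
    kind.assign(k.begin(), k.end());
    row.assign(r.begin(), r.end());
    col.assign(c.begin(), c.end());
    divs.assign(d.begin(), d.end());
    kills.assign(kl.begin(), kl.end());
    engage.assign(en.begin(), en.end());
    alive.resize(n);
    for (int i = 0; i < n; ++i) {
      alive[i] = al[i] ? 1 : 0;
      if (!alive[i]) continue;
      if (row[i] < 0 || row[i] >= H || col[i] < 0 || col[i] >= W)
        stop("agent %d position (%d,%d) outside %dx%d grid",
             i + 1, row[i], col[i], H, W);
      int& cell = occ[row[i] * W + col[i]];
      if (cell != 0)
        stop("agents %d and %d share position (%d,%d)",
             cell, i + 1, row[i], col[i]);
      cell = i + 1;
      cnt[kind[i]]++;
    }
  }

  void logEvent(int type, int k, int id, int r, int c,
                int killer = 0, int kr = -1, int kc = -1) {
    if (!recordEvents) return;
    evTick.push_back(tick + 1);        // events belong to the tick being run
    evType.push_back(type);
    evKind.push_back(k);
    evId.push_back(id + 1);
    evRow.push_back(r);
    evCol.push_back(c);
    evKiller.push_back(killer);
    evKRow.push_back(kr);
    evKCol.push_back(kc);
  }

  void die(int i) {
    occ[row[i] * W + col[i]] = 0;
    alive[i] = 0;
    cnt[kind[i]]--;
    logEvent(EV_DEATH, kind[i], i, row[i], col[i]);
  }

  void killedBy(int victim, int killer) {
    occ[row[victim] * W + col[victim]] = 0;
    alive[victim] = 0;
    cnt[kind[victim]]--;
    logEvent(EV_KILL, kind[victim], victim, row[victim], col[victim],
             killer + 1, row[killer], col[killer]);
  }

  int spawn(int k, int r, int c, int d, int kl, int en) {
    kind.push_back(k); row.push_back(r); col.push_back(c);
    divs.push_back(d); kills.push_back(kl); engage.push_back(en);
    alive.push_back(1);
    int i = (int)kind.size() - 1;
    occ[r * W + c] = i + 1;
    cnt[k]++;
    logEvent(EV_BIRTH, k, i, r, c);
    return i;
  }

  int freeNeighbors(int r, int c, int* nr, int* nc) const {
    int n = 0;
    for (int dr = -1; dr <= 1; ++dr)
      for (int dc = -1; dc <= 1; ++dc) {
        if (dr == 0 && dc == 0) continue;
        int rr = r + dr, cc = c + dc;
        if (rr < 0 || rr >= H || cc < 0 || cc >= W) continue;
        if (occ[rr * W + cc] == 0) { nr[n] = rr; nc[n] = cc; ++n; }
      }
    return n;
  }

  inline bool isTarget(int cell, bool tumorTarget) const {
    if (cell == 0) return false;
    int k = kind[cell - 1];
    return tumorTarget ? (k == 1 || k == 2) : (k == 3);
  }

  // Squared Euclidean distance from (r0,c0) to the nearest live agent of the
  // target class, by expanding Chebyshev ring search (exact: keeps scanning
  // rings until the ring radius exceeds the best Euclidean distance found).
  long long nearestSqDist(int r0, int c0, bool tumorTarget) const {
    int navail = tumorTarget ? (cnt[1] + cnt[2]) : cnt[3];
    if (navail == 0) return -1;
    long long best = LLONG_MAX;
    int dmax = std::max(W, H);
    for (int d = 1; d <= dmax; ++d) {
      if ((long long)d * d > best) break;
      int rlo = r0 - d, rhi = r0 + d, clo = c0 - d, chi = c0 + d;
      // top and bottom rows of the ring
      for (int rr = rlo; rr <= rhi; rr += (rhi - rlo > 0 ? rhi - rlo : 1)) {
        if (rr < 0 || rr >= H) { if (rhi == rlo) break; continue; }
        int cfrom = std::max(clo, 0), cto = std::min(chi, W - 1);
        for (int cc = cfrom; cc <= cto; ++cc)
          if (isTarget(occ[rr * W + cc], tumorTarget)) {
            long long dd = (long long)(rr - r0) * (rr - r0) +
                           (long long)(cc - c0) * (cc - c0);
            if (dd < best) best = dd;
          }
        if (rhi == rlo) break;
      }
      // left and right columns, excluding corners already scanned
      for (int cc = clo; cc <= chi; cc += (chi - clo > 0 ? chi - clo : 1)) {
        if (cc < 0 || cc >= W) { if (chi == clo) break; continue; }
        int rfrom = std::max(rlo + 1, 0), rto = std::min(rhi - 1, H - 1);
        for (int rr = rfrom; rr <= rto; ++rr)
          if (isTarget(occ[rr * W + cc], tumorTarget)) {
            long long dd = (long long)(rr - r0) * (rr - r0) +
                           (long long)(cc - c0) * (cc - c0);
            if (dd < best) best = dd;
          }
        if (chi == clo) break;
      }
    }
    return best == LLONG_MAX ? -1 : best;
  }

  // Pick a migration destination among free Moore neighbors: uniformly random,
  // or the neighbor minimizing distance to the nearest target agent (ties
  // broken uniformly). Falls back to uniform when no target exists.
  bool pickStep(int r, int c, bool directed, bool tumorTarget,
                int& outR, int& outC) {
    int nr[8], nc[8];
    int n = freeNeighbors(r, c, nr, nc);
    if (n == 0) return false;
    if (directed) {
      int navail = tumorTarget ? (cnt[1] + cnt[2]) : cnt[3];
      if (navail > 0) {
        long long best = LLONG_MAX;
        int cand[8], ncand = 0;
        for (int i = 0; i < n; ++i) {
          long long d = nearestSqDist(nr[i], nc[i], tumorTarget);
          if (d < best) { best = d; ncand = 0; cand[ncand++] = i; }
          else if (d == best) cand[ncand++] = i;
        }
        int pick = cand[ncand == 1 ? 0 : runifInt(ncand)];
        outR = nr[pick]; outC = nc[pick];
        return true;
      }
    }
    int pick = runifInt(n);
    outR = nr[pick]; outC = nc[pick];
    return true;
  }

  void moveTo(int i, int r, int c) {
    occ[row[i] * W + col[i]] = 0;
    row[i] = r; col[i] = c;
    occ[r * W + c] = i + 1;
  }

  bool tumorAdjacent(int r, int c) const {
    for (int dr = -1; dr <= 1; ++dr)
      for (int dc = -1; dc <= 1; ++dc) {
        if (dr == 0 && dc == 0) continue;
        int rr = r + dr, cc = c + dc;
        if (rr < 0 || rr >= H || cc < 0 || cc >= W) continue;
        int cell = occ[rr * W + cc];
        if (cell != 0 && (kind[cell - 1] == 1 || kind[cell - 1] == 2))
          return true;
      }
    return false;
  }

  // Sequential per-tick resolution: death, then proliferation (falls through
  // to migration when blocked), then migration, else idle.
  void actTumor(int i) {
    bool res = (kind[i] == 2);
    if (unif_rand() < p.TUpdeath) { die(i); return; }
    double pp = res ? p.TUpprolres
                    : p.TUpprol + (cnt[5] > 0 ? p.M2TUadd : 0.0);
    if (pp > 1.0) pp = 1.0;
    if (unif_rand() < pp && divs[i] > 0) {
      int nr[8], nc[8];
      int n = freeNeighbors(row[i], col[i], nr, nc);
      if (n > 0) {
        int pick = runifInt(n);
        divs[i]--;
        int dkind = kind[i], ddivs = divs[i];
        if (!res && p.TUpres > 0 && unif_rand() < p.TUpres) {
          dkind = 2;
          ddivs = p.TUpmaxres;
        }
        spawn(dkind, nr[pick], nc[pick], ddivs, 0, 0);
        return;
      }
    }
    double pm = res ? p.TUpmigres : p.TUpmig;
    if (unif_rand() < pm) {
      bool directed = !(unif_rand() < p.TUrwalk);
      int r, c;
      if (pickStep(row[i], col[i], directed, /*tumorTarget=*/false, r, c))
        moveTo(i, r, c);
    }
  }

  void actFibroblast(int i) {
    if (unif_rand() < p.Fpdeath) { die(i); return; }
    if (unif_rand() < p.Fpprol && divs[i] != 0) {   // divs == -1: unlimited
      int nr[8], nc[8];
      int n = freeNeighbors(row[i], col[i], nr, nc);
      if (n > 0) {
        int pick = runifInt(n);
        if (divs[i] > 0) divs[i]--;
        spawn(3, nr[pick], nc[pick], divs[i], 0, 0);
        return;
      }
    }
    if (unif_rand() < p.Fpmig) {
      bool directed = !(unif_rand() < p.Frwalk);
      int r, c;
      if (pickStep(row[i], col[i], directed, /*tumorTarget=*/true, r, c))
        moveTo(i, r, c);
    }
  }

  void actMacrophage(int i) {
    bool m1 = (kind[i] == 4);
    double pkill = m1 ? p.M1pkill : p.M2pkill;
    double pmig  = m1 ? p.M1pmig  : p.M2pmig;
    double rwalk = m1 ? p.M1rwalk : p.M2rwalk;
    int speed    = m1 ? p.M1speed : p.M2speed;
    int duration = m1 ? p.M1engagementDuration : p.M2engagementDuration;

    if (engage[i] > 0) {                     // engaged: recover, do nothing
      engage[i] -= speed;
      if (engage[i] < 0) engage[i] = 0;
      return;
    }
    if (p.Mpdeath > 0 && unif_rand() < p.Mpdeath) { die(i); return; }
    if (kills[i] > 0) {
      int victims[8], nv = 0;
      for (int dr = -1; dr <= 1; ++dr)
        for (int dc = -1; dc <= 1; ++dc) {
          if (dr == 0 && dc == 0) continue;
          int rr = row[i] + dr, cc = col[i] + dc;
          if (rr < 0 || rr >= H || cc < 0 || cc >= W) continue;
          int cell = occ[rr * W + cc];
          if (cell != 0 && (kind[cell - 1] == 1 || kind[cell - 1] == 2))
            victims[nv++] = cell - 1;
        }
      if (nv > 0 && unif_rand() < pkill) {
        int v = victims[nv == 1 ? 0 : runifInt(nv)];
        killedBy(v, i);
        kills[i]--;
        engage[i] = duration;
        return;
      }
    }
    if (unif_rand() < pmig) {
      for (int s = 0; s < speed; ++s) {
        if (tumorAdjacent(row[i], col[i])) break;
        bool directed = !(unif_rand() < rwalk);
        int r, c;
        if (!pickStep(row[i], col[i], directed, /*tumorTarget=*/true, r, c))
          break;
        moveTo(i, r, c);
      }
    }
  }

  void act(int i) {
    switch (kind[i]) {
      case 1: case 2: actTumor(i); break;
      case 3: actFibroblast(i); break;
      case 4: case 5: actMacrophage(i); break;
      default: stop("unknown agent kind %d", kind[i]);
    }
  }

  void shuffled(std::vector<int>& ids) {
    for (int i = (int)ids.size() - 1; i > 0; --i) {
      int j = runifInt(i + 1);
      std::swap(ids[i], ids[j]);
    }
  }

  // One 4-hour tick: tumor cells (sensitive + resistant together), then
  // fibroblasts, then M1, then M2. Agents born during the tick (index >= n0)
  // do not act until the next tick.
  void step() {
    int n0 = (int)kind.size();
    static const int groups[4][2] = {{1, 2}, {3, 3}, {4, 4}, {5, 5}};
    std::vector<int> ids;
    for (int g = 0; g < 4; ++g) {
      ids.clear();
      for (int i = 0; i < n0; ++i)
        if (alive[i] && (kind[i] == groups[g][0] || kind[i] == groups[g][1]))
          ids.push_back(i);
      shuffled(ids);
      for (size_t k = 0; k < ids.size(); ++k)
        if (alive[ids[k]]) act(ids[k]);
    }
    tick++;
  }

  IntegerMatrix snapshot() const {
    IntegerMatrix m(H, W);
    for (int r = 0; r < H; ++r)
      for (int c = 0; c < W; ++c) {
        int cell = occ[r * W + c];
        m(r, c) = cell == 0 ? 0 : kind[cell - 1];
      }
    return m;
  }

  List stateList() const {
    int n = (int)kind.size();
    LogicalVector al(n);
    for (int i = 0; i < n; ++i) al[i] = alive[i] != 0;
    return List::create(
      _["kind"] = IntegerVector(kind.begin(), kind.end()),
      _["row"] = IntegerVector(row.begin(), row.end()),
      _["col"] = IntegerVector(col.begin(), col.end()),
      _["divs"] = IntegerVector(divs.begin(), divs.end()),
      _["kills"] = IntegerVector(kills.begin(), kills.end()),
      _["engage"] = IntegerVector(engage.begin(), engage.end()),
      _["alive"] = al,
      _["tick"] = tick);
  }

  DataFrame eventsFrame() const {
    return DataFrame::create(
      _["tick"] = IntegerVector(evTick.begin(), evTick.end()),
      _["event"] = IntegerVector(evType.begin(), evType.end()),
      _["kind"] = IntegerVector(evKind.begin(), evKind.end()),
      _["id"] = IntegerVector(evId.begin(), evId.end()),
      _["row"] = IntegerVector(evRow.begin(), evRow.end()),
      _["col"] = IntegerVector(evCol.begin(), evCol.end()),
      _["killer_id"] = IntegerVector(evKiller.begin(), evKiller.end()),
      _["killer_row"] = IntegerVector(evKRow.begin(), evKRow.end()),
      _["killer_col"] = IntegerVector(evKCol.begin(), evKCol.end()));
  }
};

Sim makeSim(int width, int height, const List& state, const List& params) {
  Sim sim(width, height, paramsFromList(params));
  sim.tick = as<int>(state["tick"]);
  sim.loadAgents(state["kind"], state["row"], state["col"], state["divs"],
                 state["kills"], state["engage"], state["alive"]);
  return sim;
}

} // namespace

// [[Rcpp::export]]
List cpp_simulate(int width, int height, List state, List params,
                  int n_ticks, IntegerVector snapshot_ticks,
                  bool record_events) {
  Sim sim = makeSim(width, height, state, params);
  sim.recordEvents = record_events;

  std::vector<bool> wantSnap(sim.tick + n_ticks + 1, false);
  for (int i = 0; i < snapshot_ticks.size(); ++i) {
    int t = snapshot_ticks[i];
    if (t >= sim.tick && t <= sim.tick + n_ticks) wantSnap[t] = true;
  }
  List snaps;
  CharacterVector snapNames;
  if (wantSnap[sim.tick]) {
    snaps.push_back(sim.snapshot());
    snapNames.push_back(std::to_string(sim.tick));
  }

  IntegerMatrix counts(n_ticks + 1, 5);
  IntegerVector ticksOut(n_ticks + 1);
  for (int k = 0; k < 5; ++k) counts(0, k) = sim.cnt[k + 1];
  ticksOut[0] = sim.tick;

  for (int t = 0; t < n_ticks; ++t) {
    sim.step();
    for (int k = 0; k < 5; ++k) counts(t + 1, k) = sim.cnt[k + 1];
    ticksOut[t + 1] = sim.tick;
    if (wantSnap[sim.tick]) {
      snaps.push_back(sim.snapshot());
      snapNames.push_back(std::to_string(sim.tick));
    }
    if (t % 64 == 0) Rcpp::checkUserInterrupt();
  }
  if (snaps.size() > 0) snaps.attr("names") = snapNames;

  colnames(counts) = CharacterVector::create(
    "tumor", "tumor_resistant", "fibroblast", "M1", "M2");
  return List::create(
    _["state"] = sim.stateList(),
    _["ticks"] = ticksOut,
    _["counts"] = counts,
    _["snapshots"] = snaps,
    _["events"] = sim.eventsFrame());
}

// [[Rcpp::export]]
List cpp_resolve_agent(int width, int height, List state, List params,
                       int agent) {
  Sim sim = makeSim(width, height, state, params);
  sim.recordEvents = true;
  if (agent < 1 || agent > (int)sim.kind.size())
    stop("agent index %d out of range", agent);
  if (!sim.alive[agent - 1]) stop("agent %d is not alive", agent);
  sim.act(agent - 1);
  return List::create(
    _["state"] = sim.stateList(),
    _["events"] = sim.eventsFrame());
}
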