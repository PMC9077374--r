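// Independent Reaction Times event engine.
//
// Works in simulation units (nm, ps). Particle positions are the 1-ps
// birth positions; pair reaction times are drawn from the Smoluchowski
// first-passage law using the separation at channel-creation time, with
// the clock reset for channels created by reaction products (the standard
// IRT secondary-reaction approximation). Uses R's RNG stream so results
// are reproducible from set.seed().

#include <Rcpp.h>
#include <queue>
#include <unordered_map>
#include <vector>
#include <cmath>

using namespace Rcpp;

namespace {

struct Event {
  double t;
  int i, j;    // j = -1 for first-order channels
  int rid;     // 0-based reaction row
  bool operator>(const Event& o) const { return t > o.t; }
};

struct PairChan {
  double R, D;  // encounter radius (nm), mutual diffusion (nm^2/ps)
  int rid;
};

inline double erfcinv(double y) {
  // erfc(x) = 2*Phi(-x*sqrt(2))  =>  erfcinv(y) = -qnorm(y/2)/sqrt(2)
  return -R::qnorm(0.5 * y, 0.0, 1.0, 1, 0) * M_SQRT1_2;
}

inline long long cellKey(int cx, int cy, int cz) {
  return (static_cast<long long>(cx) & 0x1FFFFF) |
         ((static_cast<long long>(cy) & 0x1FFFFF) << 21) |
         ((static_cast<long long>(cz) & 0x1FFFFF) << 42);
}

struct Engine {
  // geometry / state
  std::vector<double> px, py, pz;
  std::vector<int> spec;
  std::vector<char> alive;
  double cell;  // grid cell size = interaction cutoff
  std::unordered_map<long long, std::vector<int> > grid;

  // chemistry tables
  int nspecies;
  std::vector<std::vector<PairChan> > chan;   // indexed a*nspecies+b
  std::vector<double> foTot;                  // per species, ps^-1
  std::vector<std::vector<std::pair<double,int> > > foChan; // (rate, rid)
  std::vector<std::vector<int> > products;    // per reaction, track species
  std::vector<double> Dspec;                  // per species, nm^2/ps

  double t_end;
  std::priority_queue<Event, std::vector<Event>, std::greater<Event> > heap;

  void addToGrid(int i) {
    int cx = (int)std::floor(px[i] / cell);
    int cy = (int)std::floor(py[i] / cell);
    int cz = (int)std::floor(pz[i] / cell);
    grid[cellKey(cx, cy, cz)].push_back(i);
  }

  void samplePair(int i, int j, double t0) {
    const std::vector<PairChan>& cc = chan[spec[i] * nspecies + spec[j]];
    if (cc.empty()) return;
    double dx = px[i] - px[j], dy = py[i] - py[j], dz = pz[i] - pz[j];
    double r = std::sqrt(dx * dx + dy * dy + dz * dz);
    if (r > cell) return;
    for (size_t c = 0; c < cc.size(); ++c) {
      const PairChan& pc = cc[c];
      double t;
      if (r <= pc.R) {
        // contact rule: born overlapping -> react immediately after birth
        // (just past the snapshot, so the birth-time yields stay intact)
        t = t0 + 1e-6;
      } else {
        double u = unif_rand();
        double w = u * r / pc.R;
        if (w >= 1.0) continue;  // non-reactive draw (prob 1 - R/r)
        double xi = erfcinv(w);
        t = t0 + (r - pc.R) * (r - pc.R) / (4.0 * pc.D * xi * xi);
      }
      if (t <= t_end) {
        Event e; e.t = t; e.i = i; e.j = j; e.rid = pc.rid;
        heap.push(e);
      }
    }
  }

  // sample channels of a newly introduced particle against all previously
  // introduced live particles within the cutoff, plus its first-order clock
  void seedParticle(int i, double t0) {
    int cx = (int)std::floor(px[i] / cell);
    int cy = (int)std::floor(py[i] / cell);
    int cz = (int)std::floor(pz[i] / cell);
    for (int ax = cx - 1; ax <= cx + 1; ++ax)
      for (int ay = cy - 1; ay <= cy + 1; ++ay)
        for (int az = cz - 1; az <= cz + 1; ++az) {
          std::unordered_map<long long, std::vector<int> >::iterator it =
            grid.find(cellKey(ax, ay, az));
          if (it == grid.end()) continue;
          const std::vector<int>& cellv = it->second;
          for (size_t q = 0; q < cellv.size(); ++q) {
            int j = cellv[q];
            if (j != i && alive[j]) samplePair(i, j, t0);
          }
        }
    addToGrid(i);
    double lam = foTot[spec[i]];
    if (lam > 0.0) {
      double t = t0 + exp_rand() / lam;
      if (t <= t_end) {
        // competing exponentials: channel picked proportionally to rate
        double v = unif_rand() * lam;
        const std::vector<std::pair<double,int> >& fc = foChan[spec[i]];
        int rid = fc.back().second;
        for (size_t c = 0; c < fc.size(); ++c) {
          v -= fc[c].first;
          if (v <= 0.0) { rid = fc[c].second; break; }
        }
        Event e; e.t = t; e.i = i; e.j = -1; e.rid = rid;
        heap.push(e);
      }
    }
  }
};

}  // namespace

// [[Rcpp::export(name = ".irt_run_history_cpp")]]
List irt_run_history_cpp(NumericMatrix pos, IntegerVector spec0,
                         int nspecies,
                         IntegerVector pc_a, IntegerVector pc_b,
                         NumericVector pc_R, NumericVector pc_D,
                         IntegerVector pc_rid,
                         IntegerVector fo_spec, NumericVector fo_rate,
                         IntegerVector fo_rid,
                         List products, NumericVector D_spec,
                         double t_start, double t_end, double cutoff) {
  int n0 = pos.nrow();
  Engine eng;
  eng.nspecies = nspecies;
  eng.cell = cutoff;
  eng.t_end = t_end;
  eng.chan.assign(nspecies * nspecies, std::vector<PairChan>());
  for (int c = 0; c < pc_a.size(); ++c) {
    PairChan pc; pc.R = pc_R[c]; pc.D = pc_D[c]; pc.rid = pc_rid[c];
    eng.chan[pc_a[c] * nspecies + pc_b[c]].push_back(pc);
    if (pc_a[c] != pc_b[c])
      eng.chan[pc_b[c] * nspecies + pc_a[c]].push_back(pc);
  }
  eng.foTot.assign(nspecies, 0.0);
  eng.foChan.assign(nspecies, std::vector<std::pair<double,int> >());
  for (int c = 0; c < fo_spec.size(); ++c) {
    eng.foTot[fo_spec[c]] += fo_rate[c];
    eng.foChan[fo_spec[c]].push_back(std::make_pair(fo_rate[c], fo_rid[c]));
  }
  eng.products.resize(products.size());
  for (int r = 0; r < products.size(); ++r) {
    IntegerVector pv = products[r];
    eng.products[r].assign(pv.begin(), pv.end());
  }
  eng.Dspec.assign(D_spec.begin(), D_spec.end());

  eng.px.reserve(2 * n0 + 16); eng.py.reserve(2 * n0 + 16);
  eng.pz.reserve(2 * n0 + 16);
  for (int i = 0; i < n0; ++i) {
    eng.px.push_back(pos(i, 0));
    eng.py.push_back(pos(i, 1));
    eng.pz.push_back(pos(i, 2));
    eng.spec.push_back(spec0[i]);
    eng.alive.push_back(1);
    eng.seedParticle(i, t_start);  // pairs only vs already-seeded: each once
  }

  std::vector<double> ev_t, ev_x, ev_y, ev_z;
  std::vector<int> ev_r;

  while (!eng.heap.empty()) {
    Event e = eng.heap.top();
    eng.heap.pop();
    if (!eng.alive[e.i]) continue;
    if (e.j >= 0 && !eng.alive[e.j]) continue;

    double ex, ey, ez;
    if (e.j >= 0) {
      double Da = eng.Dspec[eng.spec[e.i]], Db = eng.Dspec[eng.spec[e.j]];
      double w = Da / (Da + Db);  // product sits nearer the slower parent
      ex = eng.px[e.i] + w * (eng.px[e.j] - eng.px[e.i]);
      ey = eng.py[e.i] + w * (eng.py[e.j] - eng.py[e.i]);
      ez = eng.pz[e.i] + w * (eng.pz[e.j] - eng.pz[e.i]);
      eng.alive[e.j] = 0;
    } else {
      ex = eng.px[e.i]; ey = eng.py[e.i]; ez = eng.pz[e.i];
    }
    eng.alive[e.i] = 0;

    ev_t.push_back(e.t); ev_r.push_back(e.rid + 1);
    ev_x.push_back(ex); ev_y.push_back(ey); ev_z.push_back(ez);

    const std::vector<int>& pr = eng.products[e.rid];
    for (size_t p = 0; p < pr.size(); ++p) {
      int k = (int)eng.px.size();
      eng.px.push_back(ex); eng.py.push_back(ey); eng.pz.push_back(ez);
      eng.spec.push_back(pr[p]);
      eng.alive.push_back(1);
      eng.seedParticle(k, e.t);
    }
  }

  int nalive = 0;
  for (size_t i = 0; i < eng.alive.size(); ++i) nalive += eng.alive[i];
  IntegerVector surv(nalive);
  int s = 0;
  for (size_t i = 0; i < eng.alive.size(); ++i)
    if (eng.alive[i]) surv[s++] = eng.spec[i] + 1;

  int ne = (int)ev_t.size();
  NumericMatrix events(ne, 5);
  for (int i = 0; i < ne; ++i) {
    events(i, 0) = ev_t[i]; events(i, 1) = ev_r[i];
    events(i, 2) = ev_x[i]; events(i, 3) = ev_y[i]; events(i, 4) = ev_z[i];
  }
  return List::create(_["events"] = events, _["survivors"] = surv);
}
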