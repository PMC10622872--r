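// MCMC engine for the multispecies coalescent with migration (MSC-M).
//
// State: parameters Theta = (tau, theta, M) plus one gene tree with an
// explicit migration history per locus.  The joint target is
// p(Theta) p(G|Theta) p(X|G)^beta, with beta = 1 for ordinary posterior
// sampling and beta in (0,1) for power posteriors (thermodynamic
// integration).  Migration rates of inactive entries are retained as
// pseudo-parameters with pseudo-prior equal to the prior (composite-space
// construction), so divergence-time proposals may flip entries between
// active and inactive.
//
// Gene-tree representation per locus: node arrays (parent/children/time/pop)
// and, per node, the ordered migration events on the branch above it as
// (time, to-population) pairs; between events a lineage is implicitly
// promoted to the ancestral population when it crosses a species divergence.
// The density is accumulated through per-locus sufficient statistics
// (coalescent counts, pair-time exposures, migration counts, active
// lineage-time exposures), so parameter updates cost O(1) per locus.

#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <random>
#include <algorithm>
#include <limits>

using namespace Rcpp;

static const double INF = std::numeric_limits<double>::infinity();

struct MigEv { double t; int to; };

struct Loc {
  int ntip = 0, nnode = 0, npat = 0;
  std::vector<int> parent, c0, c1, pop;
  std::vector<double> time;
  std::vector<std::vector<MigEv>> ev;
  // data (site patterns, tip-major: pat[j*ntip + i] for pattern j, tip i)
  std::vector<int> pat;
  std::vector<double> cnt;
  double h = 1.0;
  // caches
  std::vector<double> A;   // per pop: sum n(n-1) dt
  std::vector<int> cc;     // per pop: coalescent count
  std::vector<int> w;      // per entry: migration count
  std::vector<double> b;   // per entry: sum n_dst dt over active time
  double logl = 0.0;
};

struct LocSnap {
  std::vector<int> parent, c0, c1, pop;
  std::vector<double> time;
  std::vector<std::vector<MigEv>> ev;
  std::vector<double> A; std::vector<int> cc, w; std::vector<double> b;
  double logl;
};

struct MoveStat { long att = 0, acc = 0; double step = 0; };

class Engine {
public:
  // model
  int nsp, npop, nmig, root, k_nonroot;
  std::vector<int> pparent;
  std::vector<double> tau, theta;
  std::vector<int> msrc, mdst;
  std::vector<double> M;
  double a_th, b_th, a_ta, b_ta, a_mg, b_mg;
  // loci
  std::vector<Loc> loc;
  int L;
  // aggregates over loci (per pop / per entry, with 1/h folded in)
  std::vector<double> Sc, SA, Sw, Sb;
  double total_logG = 0, total_logl = 0;
  // settings
  bool use_lik = true;
  double beta = 1.0;
  int kernel = 0;             // 0 extended rubber-band, 1 rejection
  bool broken_hastings = false;
  bool theta_in_mixing = false;
  int spr_per_locus = 1;
  // move statistics (0 theta, 1 migrate, 2 migtime, 3 tau, 4 mix, 5 spr)
  MoveStat st[6];

  std::mt19937_64 rng;
  std::uniform_real_distribution<double> unif{0.0, 1.0};

  double U() { return unif(rng); }
  double rexp1(double rate) {
    return -std::log(1.0 - U()) / rate;
  }
  double rgamma1(double shape, double rate) {
    std::gamma_distribution<double> g(shape, 1.0 / rate);
    return g(rng);
  }

  double lo(int p) const { return p < nsp ? 0.0 : tau[p]; }
  double up(int p) const { return pparent[p] < 0 ? INF : tau[pparent[p]]; }
  int popup(int p, double t) const {
    while (pparent[p] >= 0 && tau[pparent[p]] <= t) p = pparent[p];
    return p;
  }
  double winlo(int e) const { return std::max(lo(msrc[e]), lo(mdst[e])); }
  double winup(int e) const { return std::min(up(msrc[e]), up(mdst[e])); }
  bool active(int e) const { return winlo(e) < winup(e); }
  int entry_of(int src, int dst) const {
    for (int e = 0; e < nmig; e++)
      if (msrc[e] == src && mdst[e] == dst) return e;
    return -1;
  }

  // ---- density sufficient statistics --------------------------------------

  // walk the branch above node v, reporting (t0,t1,pop) segments and the
  // from-population of each migration event; returns end population or -1 on
  // inconsistency.
  template <class SegFn, class EvFn>
  int walk(const Loc& lc, int v, SegFn seg, EvFn evfn) const {
    int pa = lc.parent[v];
    double t = lc.time[v], tend = lc.time[pa];
    int p = lc.pop[v];
    for (const MigEv& e : lc.ev[v]) {
      if (e.t <= t || e.t >= tend) return -1;
      while (up(p) <= e.t) { seg(t, up(p), p); t = up(p); p = pparent[p]; }
      seg(t, e.t, p);
      evfn(e.t, p, e.to);
      t = e.t; p = e.to;
      if (!(lo(p) <= t && t < up(p))) return -1;
    }
    while (up(p) <= tend) { seg(t, up(p), p); t = up(p); p = pparent[p]; }
    seg(t, tend, p);
    return p;
  }

  bool check_loc(const Loc& lc) const {
    int rt = -1;
    for (int v = 0; v < lc.nnode; v++) {
      if (lc.parent[v] < 0) { if (rt >= 0) return false; rt = v; }
      int p = lc.pop[v];
      if (!(lo(p) <= lc.time[v] && lc.time[v] < up(p))) return false;
      if (lc.parent[v] >= 0 && lc.time[v] >= lc.time[lc.parent[v]])
        return false;
    }
    if (rt < 0) return false;
    for (int v = 0; v < lc.nnode; v++) {
      if (lc.parent[v] < 0) continue;
      bool ok = true;
      int end = walk(lc, v, [](double, double, int) {},
                     [&](double t, int f, int to) {
                       int e = entry_of(to, f);
                       if (e < 0 || t < winlo(e) || t >= winup(e)) ok = false;
                     });
      if (!ok || end < 0 || end != lc.pop[lc.parent[v]]) return false;
    }
    return true;
  }

  void recompute_stats(Loc& lc) const {
    std::fill(lc.A.begin(), lc.A.end(), 0.0);
    std::fill(lc.cc.begin(), lc.cc.end(), 0);
    std::fill(lc.w.begin(), lc.w.end(), 0);
    std::fill(lc.b.begin(), lc.b.end(), 0.0);
    for (int v = lc.ntip; v < lc.nnode; v++) lc.cc[lc.pop[v]]++;
    // lineage segments
    static thread_local std::vector<double> s0, s1;
    static thread_local std::vector<int> sp;
    s0.clear(); s1.clear(); sp.clear();
    double maxT = 0;
    for (int v = 0; v < lc.nnode; v++) maxT = std::max(maxT, lc.time[v]);
    for (int v = 0; v < lc.nnode; v++) {
      if (lc.parent[v] < 0) continue;
      int end = walk(lc, v,
        [&](double a, double bb, int p) {
          if (bb > a) { s0.push_back(a); s1.push_back(bb); sp.push_back(p); }
        },
        [&](double t, int f, int to) {
          int e = entry_of(to, f);
          if (e >= 0) lc.w[e]++; else stop("event without matching entry");
        });
      if (end < 0) stop("inconsistent lineage path in stats");
    }
    // breakpoints: segment ends + divergence times
    static thread_local std::vector<double> bp;
    bp.clear();
    bp.insert(bp.end(), s0.begin(), s0.end());
    bp.insert(bp.end(), s1.begin(), s1.end());
    for (int p = nsp; p < npop; p++)
      if (tau[p] > 0 && tau[p] < maxT) bp.push_back(tau[p]);
    std::sort(bp.begin(), bp.end());
    bp.erase(std::unique(bp.begin(), bp.end()), bp.end());
    static thread_local std::vector<int> nj;
    nj.assign(npop, 0);
    size_t nseg = s0.size();
    // sweep
    for (size_t k = 0; k + 1 < bp.size(); k++) {
      double x0 = bp[k], x1 = bp[k + 1], dt = x1 - x0;
      if (dt <= 0) continue;
      std::fill(nj.begin(), nj.end(), 0);
      for (size_t i = 0; i < nseg; i++)
        if (s0[i] <= x0 && s1[i] >= x1) nj[sp[i]]++;
      for (int j = 0; j < npop; j++)
        if (nj[j] > 1) lc.A[j] += (double)nj[j] * (nj[j] - 1) * dt;
      for (int e = 0; e < nmig; e++) {
        int j = mdst[e];
        if (nj[j] > 0 && x0 >= winlo(e) && x1 <= winup(e))
          lc.b[e] += (double)nj[j] * dt;
      }
    }
  }

  double logG_from(const std::vector<double>& A, const std::vector<int>& cc,
                   const std::vector<int>& w, const std::vector<double>& b,
                   double h) const {
    double lg = 0;
    for (int j = 0; j < npop; j++) {
      double th = theta[j] * h;
      if (cc[j] > 0) lg += cc[j] * std::log(2.0 / th);
      lg -= A[j] / th;
    }
    for (int e = 0; e < nmig; e++) {
      double th = theta[mdst[e]] * h;
      if (w[e] > 0) {
        if (M[e] <= 0) return -INF;
        lg += w[e] * std::log(4.0 * M[e] / th);
      }
      lg -= 4.0 * M[e] * b[e] / th;
    }
    return lg;
  }
  double logG_loc(const Loc& lc) const {
    return logG_from(lc.A, lc.cc, lc.w, lc.b, lc.h);
  }

  void rebuild_aggregates() {
    Sc.assign(npop, 0.0); SA.assign(npop, 0.0);
    Sw.assign(nmig, 0.0); Sb.assign(nmig, 0.0);
    for (const Loc& lc : loc) {
      for (int j = 0; j < npop; j++) {
        Sc[j] += lc.cc[j];
        SA[j] += lc.A[j] / lc.h;
      }
      for (int e = 0; e < nmig; e++) {
        Sw[e] += lc.w[e];
        Sb[e] += lc.b[e] / lc.h;
      }
    }
  }
  void agg_update(const Loc& lc, double sign) {
    for (int j = 0; j < npop; j++) {
      Sc[j] += sign * lc.cc[j];
      SA[j] += sign * lc.A[j] / lc.h;
    }
    for (int e = 0; e < nmig; e++) {
      Sw[e] += sign * lc.w[e];
      Sb[e] += sign * lc.b[e] / lc.h;
    }
  }

  double recompute_total_logG() {
    double lg = 0;
    for (Loc& lc : loc) lg += logG_loc(lc);
    return lg;
  }

  // ---- JC69 pruning likelihood --------------------------------------------

  std::vector<double> clv, scal;  // scratch

  double prune(const Loc& lc) {
    if (!use_lik || lc.npat == 0) return 0.0;
    int nn = lc.nnode, np = lc.npat;
    clv.assign((size_t)nn * np * 4, 0.0);
    scal.assign(np, 0.0);
    // postorder
    static thread_local std::vector<int> order, stackv;
    order.clear(); stackv.clear();
    int rt = 0;
    for (int v = 0; v < nn; v++) if (lc.parent[v] < 0) rt = v;
    stackv.push_back(rt);
    while (!stackv.empty()) {
      int v = stackv.back(); stackv.pop_back();
      order.push_back(v);
      if (v >= lc.ntip) { stackv.push_back(lc.c0[v]); stackv.push_back(lc.c1[v]); }
    }
    std::reverse(order.begin(), order.end());
    for (int v : order) {
      double* cv = &clv[(size_t)v * np * 4];
      if (v < lc.ntip) {
        for (int j = 0; j < np; j++) {
          int s = lc.pat[(size_t)j * lc.ntip + v];
          if (s < 0) { cv[4 * j] = cv[4 * j + 1] = cv[4 * j + 2] = cv[4 * j + 3] = 1.0; }
          else cv[4 * j + s] = 1.0;
        }
      } else {
        int ch[2] = {lc.c0[v], lc.c1[v]};
        double pe[2], pd[2];
        for (int k = 0; k < 2; k++) {
          double bl = lc.time[v] - lc.time[ch[k]];
          double x = std::exp(-4.0 * bl / 3.0);
          pe[k] = 0.25 + 0.75 * x;   // same
          pd[k] = 0.25 - 0.25 * x;   // different
        }
        for (int j = 0; j < np; j++) {
          double out[4] = {1, 1, 1, 1};
          double mx = 0;
          for (int k = 0; k < 2; k++) {
            const double* cc_ = &clv[(size_t)ch[k] * np * 4 + 4 * j];
            double sum = cc_[0] + cc_[1] + cc_[2] + cc_[3];
            double d = pe[k] - pd[k];
            for (int s = 0; s < 4; s++) out[s] *= pd[k] * sum + d * cc_[s];
          }
          for (int s = 0; s < 4; s++) { cv[4 * j + s] = out[s]; mx = std::max(mx, out[s]); }
          if (mx > 0 && mx < 1e-200) {
            for (int s = 0; s < 4; s++) cv[4 * j + s] /= mx;
            scal[j] += std::log(mx);
          }
          // propagate child scalers
        }
      }
    }
    double lg = 0;
    const double* cr = &clv[(size_t)rt * np * 4];
    for (int j = 0; j < np; j++) {
      double site = 0.25 * (cr[4 * j] + cr[4 * j + 1] + cr[4 * j + 2] + cr[4 * j + 3]);
      lg += lc.cnt[j] * (std::log(site) + scal[j]);
    }
    return lg;
  }

  // ---- priors -------------------------------------------------------------

  double dlgamma(double x, double a, double b) const {
    return (a - 1.0) * std::log(x) - b * x;  // unnormalised, enough for ratios
  }

  // ---- moves --------------------------------------------------------------
  // per-component step sizes (tuned independently: a component whose move is
  // insensitive must not inflate the step of the others)
  std::vector<double> step_theta, step_M, step_tau;
  double step_mt = 0.001, step_mix = 0.3;
  std::vector<long> wa_th, wc_th, wa_M, wc_M, wa_ta, wc_ta;
  long wa_mt = 0, wc_mt = 0, wa_mx = 0, wc_mx = 0;

  void move_theta() {
    for (int j = 0; j < npop; j++) {
      st[0].att++; wa_th[j]++;
      double to = theta[j];
      double tn = to * std::exp(step_theta[j] * (U() - 0.5));
      double dpr = dlgamma(tn, a_th, b_th) - dlgamma(to, a_th, b_th);
      double dinv = 1.0 / tn - 1.0 / to, dlog = std::log(tn) - std::log(to);
      double dG = -Sc[j] * dlog - SA[j] * dinv;
      for (int e = 0; e < nmig; e++)
        if (mdst[e] == j) dG += -Sw[e] * dlog - 4.0 * M[e] * Sb[e] * dinv;
      double lacc = dpr + dG;
      if (!broken_hastings) lacc += dlog;  // multiplier Jacobian
      if (std::log(U()) < lacc) {
        theta[j] = tn; total_logG += dG;
        st[0].acc++; wc_th[j]++;
      }
    }
  }

  void move_migrate() {
    for (int e = 0; e < nmig; e++) {
      if (!active(e)) {  // pseudo-parameter: Gibbs refresh from (pseudo-)prior
        M[e] = rgamma1(a_mg, b_mg);
        continue;
      }
      st[1].att++; wa_M[e]++;
      double mo = M[e];
      double mn = mo + step_M[e] * (U() - 0.5);
      if (mn < 0) mn = -mn;
      if (mn == 0) continue;
      double dpr = dlgamma(mn, a_mg, b_mg) - dlgamma(mo, a_mg, b_mg);
      double dG = Sw[e] > 0 ? Sw[e] * (std::log(mn) - std::log(mo)) : 0.0;
      dG += -4.0 * Sb[e] / theta[mdst[e]] * (mn - mo);
      if (std::log(U()) < dpr + dG) {
        M[e] = mn; total_logG += dG;
        st[1].acc++; wc_M[e]++;
      }
    }
  }

  double reflect(double x, double a, double b) const {
    double w = b - a;
    double y = x - a;
    y -= std::floor(y / (2.0 * w)) * (2.0 * w);
    if (y > w) y = 2.0 * w - y;
    return a + y;
  }

  void move_migtime() {
    for (int li = 0; li < L; li++) {
      Loc& lc = loc[li];
      for (int v = 0; v < lc.nnode; v++) {
        if (lc.parent[v] < 0 || lc.ev[v].empty()) continue;
        for (size_t i = 0; i < lc.ev[v].size(); i++) {
          st[2].att++; wa_mt++;
          // from-population at event i
          double t = lc.time[v]; int p = lc.pop[v];
          for (size_t k2 = 0; k2 < i; k2++) {
            p = popup(p, lc.ev[v][k2].t);
            p = lc.ev[v][k2].to;
          }
          p = popup(p, lc.ev[v][i].t);
          int f = p, s = lc.ev[v][i].to;
          double tprev = i > 0 ? lc.ev[v][i - 1].t : lc.time[v];
          double tnext = i + 1 < lc.ev[v].size() ? lc.ev[v][i + 1].t
                                                 : lc.time[lc.parent[v]];
          double ilo = std::max(tprev, std::max(lo(f), lo(s)));
          double iup = std::min(tnext, std::min(up(f), up(s)));
          if (iup <= ilo) continue;
          double told = lc.ev[v][i].t;
          double tn = reflect(told + step_mt * (U() - 0.5), ilo, iup);
          if (tn <= ilo || tn >= iup) continue;
          agg_update(lc, -1.0);
          std::vector<double> A0 = lc.A; std::vector<int> cc0 = lc.cc, w0 = lc.w;
          std::vector<double> b0 = lc.b;
          double lg0 = logG_loc(lc);
          lc.ev[v][i].t = tn;
          recompute_stats(lc);
          double dG = logG_loc(lc) - lg0;
          if (std::log(U()) < dG) {
            total_logG += dG;
            st[2].acc++; wc_mt++;
          } else {
            lc.ev[v][i].t = told;
            lc.A = A0; lc.cc = cc0; lc.w = w0; lc.b = b0;
          }
          agg_update(lc, +1.0);
        }
      }
    }
  }

  LocSnap snap_loc(const Loc& lc) const {
    return LocSnap{lc.parent, lc.c0, lc.c1, lc.pop, lc.time, lc.ev,
                   lc.A, lc.cc, lc.w, lc.b, lc.logl};
  }
  void restore_loc(Loc& lc, const LocSnap& s) const {
    lc.parent = s.parent; lc.c0 = s.c0; lc.c1 = s.c1; lc.pop = s.pop;
    lc.time = s.time; lc.ev = s.ev;
    lc.A = s.A; lc.cc = s.cc; lc.w = s.w; lc.b = s.b; lc.logl = s.logl;
  }

  // rubber-band update of tau[X]; extended variant rescales migration times,
  // rejection variant leaves them and relies on the validity check.
  void move_tau_node(int X) {
    st[3].att++; wa_ta[X - nsp]++;
    double step_here = step_tau[X - nsp];
    int cA = -1, cB = -1;
    for (int p = 0; p < npop; p++) {
      if (pparent[p] == X) { if (cA < 0) cA = p; else cB = p; }
    }
    double tl = std::max(cA < nsp ? 0.0 : tau[cA], cB < nsp ? 0.0 : tau[cB]);
    bool isroot = (pparent[X] < 0);
    double tu = isroot ? INF : tau[pparent[X]];
    double tc = tau[X];
    double tn;
    if (isroot) {
      tn = tc + step_here * (U() - 0.5);
      while (tn < tl) tn = 2.0 * tl - tn;
      if (tn == tl) return;
    } else {
      if (tu <= tl) return;
      tn = reflect(tc + step_here * (U() - 0.5), tl, tu);
      if (tn <= tl || tn >= tu) return;
    }
    double rl = (tc > tl) ? (tn - tl) / (tc - tl) : 1.0;
    double ru = (!isroot && tu > tc) ? (tu - tn) / (tu - tc) : 1.0;
    double shift = tn - tc;
    long njl = 0, nju = 0;
    std::vector<LocSnap> snaps(L);
    std::vector<char> nodes_changed(L, 0);
    double old_logG = 0;
    for (int li = 0; li < L; li++) {
      old_logG += logG_loc(loc[li]);
      snaps[li] = snap_loc(loc[li]);
    }
    auto in_set = [&](int p) { return p == X || p == cA || p == cB; };
    for (int li = 0; li < L; li++) {
      Loc& lc = loc[li];
      for (int v = lc.ntip; v < lc.nnode; v++) {
        double t = lc.time[v]; int p = lc.pop[v];
        if ((p == cA || p == cB) && t > tl && t < tc) {
          lc.time[v] = tl + (t - tl) * rl; njl++; nodes_changed[li] = 1;
        } else if (p == X) {
          if (isroot) { lc.time[v] = t + shift; nodes_changed[li] = 1; }
          else { lc.time[v] = tu - (tu - t) * ru; nju++; nodes_changed[li] = 1; }
        }
      }
      if (kernel == 0) {
        for (int v = 0; v < lc.nnode; v++) {
          if (lc.parent[v] < 0 || lc.ev[v].empty()) continue;
          // from-pops along the branch (under the OLD times: use snapshot walk)
          double t = snaps[li].time[v]; int p = snaps[li].pop[v];
          for (size_t i = 0; i < lc.ev[v].size(); i++) {
            p = popup(p, snaps[li].ev[v][i].t);
            int f = p, to = snaps[li].ev[v][i].to;
            double te = snaps[li].ev[v][i].t;
            if ((in_set(f) || in_set(to)) && te > tl &&
                (isroot || te < tu)) {
              if (te < tc) { lc.ev[v][i].t = tl + (te - tl) * rl; njl++; }
              else if (!isroot) { lc.ev[v][i].t = tu - (tu - te) * ru; nju++; }
            }
            p = to;
          }
        }
      }
    }
    double tau_old = tau[X];
    tau[X] = tn;
    bool ok = true;
    for (int li = 0; li < L && ok; li++) ok = check_loc(loc[li]);
    double dpr = 0, dlik = 0, new_logG = 0;
    std::vector<double> newlogl(L);
    if (ok) {
      for (int li = 0; li < L; li++) recompute_stats(loc[li]);
      new_logG = recompute_total_logG();
      if (isroot) {
        dpr = dlgamma(tn, a_ta, b_ta) - dlgamma(tau_old, a_ta, b_ta)
            - k_nonroot * (std::log(tn) - std::log(tau_old));
      }
      for (int li = 0; li < L; li++) {
        if (nodes_changed[li] && use_lik) {
          newlogl[li] = prune(loc[li]);
          dlik += newlogl[li] - snaps[li].logl;
        } else newlogl[li] = snaps[li].logl;
      }
      double ljac = njl * std::log(rl) + nju * std::log(ru);
      double lacc = dpr + ljac + (new_logG - old_logG) + beta * dlik;
      if (std::log(U()) < lacc) {
        for (int li = 0; li < L; li++) loc[li].logl = newlogl[li];
        total_logG += new_logG - old_logG;
        total_logl += dlik;
        rebuild_aggregates();
        st[3].acc++; wc_ta[X - nsp]++;
        return;
      }
    }
    // reject / invalid: restore
    tau[X] = tau_old;
    for (int li = 0; li < L; li++) restore_loc(loc[li], snaps[li]);
  }

  void move_tau() {
    for (int X = nsp; X < npop; X++) move_tau_node(X);
  }

  void move_mixing() {
    st[4].att++; wa_mx++;
    double c = std::exp(step_mix * (U() - 0.5));
    long d = npop - nsp;  // internal species nodes
    for (const Loc& lc : loc) {
      d += lc.ntip - 1;
      for (const auto& evv : lc.ev) d += (long)evv.size();
    }
    if (theta_in_mixing) d += npop;
    std::vector<double> tau0 = tau, theta0 = theta;
    std::vector<LocSnap> snaps(L);
    double old_logG = 0;
    for (int li = 0; li < L; li++) {
      snaps[li] = snap_loc(loc[li]);
      old_logG += logG_loc(loc[li]);
    }
    for (int p = nsp; p < npop; p++) tau[p] *= c;
    if (theta_in_mixing) for (int p = 0; p < npop; p++) theta[p] *= c;
    for (Loc& lc : loc) {
      for (int v = lc.ntip; v < lc.nnode; v++) lc.time[v] *= c;
      for (auto& evv : lc.ev) for (auto& e : evv) e.t *= c;
    }
    double dpr = dlgamma(tau[root], a_ta, b_ta) - dlgamma(tau0[root], a_ta, b_ta)
               - k_nonroot * std::log(c);
    if (theta_in_mixing)
      for (int p = 0; p < npop; p++)
        dpr += dlgamma(theta[p], a_th, b_th) - dlgamma(theta0[p], a_th, b_th);
    double dlik = 0;
    std::vector<double> newlogl(L);
    for (int li = 0; li < L; li++) {
      recompute_stats(loc[li]);
      if (use_lik) {
        newlogl[li] = prune(loc[li]);
        dlik += newlogl[li] - snaps[li].logl;
      } else newlogl[li] = 0;
    }
    double new_logG = recompute_total_logG();
    double lacc = dpr + d * std::log(c) + (new_logG - old_logG) + beta * dlik;
    if (std::log(U()) < lacc) {
      for (int li = 0; li < L; li++) loc[li].logl = newlogl[li];
      total_logG += new_logG - old_logG;
      total_logl += dlik;
      rebuild_aggregates();
      st[4].acc++; wc_mx++;
    } else {
      tau = tau0; theta = theta0;
      for (int li = 0; li < L; li++) restore_loc(loc[li], snaps[li]);
    }
  }

  // regraft-by-simulation: detach the branch above a random node and
  // re-simulate its backward path of migration and coalescence given the
  // remaining lineages; the proposal is the exact conditional of the path
  // given the rest, so the acceptance ratio is the likelihood ratio.
  void move_spr(int li) {
    Loc& lc = loc[li];
    st[5].att++;
    int rt = -1;
    for (int v = 0; v < lc.nnode; v++) if (lc.parent[v] < 0) rt = v;
    int u = std::min((int)(U() * (lc.nnode - 1)), lc.nnode - 2);
    if (u >= rt) u++;  // uniform over nodes excluding the root
    LocSnap snap = snap_loc(lc);
    int p = lc.parent[u];
    int w = (lc.c0[p] == u) ? lc.c1[p] : lc.c0[p];
    int gp = lc.parent[p];
    // detach
    if (gp >= 0) {
      lc.ev[w].insert(lc.ev[w].end(), lc.ev[p].begin(), lc.ev[p].end());
      lc.parent[w] = gp;
      if (lc.c0[gp] == p) lc.c0[gp] = w; else lc.c1[gp] = w;
    } else {
      lc.parent[w] = -1;
    }
    lc.ev[p].clear();
    // backbone root m = node with parent -1, excluding u's subtree
    int m = (gp >= 0) ? rt : w;
    lc.ev[m].clear();  // path above the backbone root carries no state
    double Tb = lc.time[m];
    // mark u's subtree
    std::vector<char> insub(lc.nnode, 0);
    { std::vector<int> stk{u};
      while (!stk.empty()) {
        int v = stk.back(); stk.pop_back(); insub[v] = 1;
        if (v >= lc.ntip) { stk.push_back(lc.c0[v]); stk.push_back(lc.c1[v]); }
      } }
    // environment subsegments (t0,t1,pop,lineage-node)
    std::vector<double> e0, e1; std::vector<int> epop, enode;
    bool envok = true;
    for (int v = 0; v < lc.nnode; v++) {
      if (insub[v] || v == m || v == p || lc.parent[v] < 0) continue;
      int end = walk(lc, v, [&](double a, double bb, int pp) {
        if (bb > a) { e0.push_back(a); e1.push_back(bb);
                      epop.push_back(pp); enode.push_back(v); }
      }, [](double, int, int) {});
      if (end < 0) envok = false;
    }
    // open lineages of the detached subtree (they ride along unchanged, but
    // the regenerated top lineage must carry a coalescence hazard against
    // them above Tb: such an event aborts the proposal, which makes the
    // proposal law the exact conditional of the regenerated paths)
    std::vector<double> s0_, s1_; std::vector<int> spop_;
    for (int v = 0; v < lc.nnode; v++) {
      if (!insub[v] || v == u) continue;
      int end = walk(lc, v, [&](double a, double bb, int pp) {
        if (bb > a) { s0_.push_back(a); s1_.push_back(bb); spop_.push_back(pp); }
      }, [](double, int, int) {});
      if (end < 0) envok = false;
    }
    if (!envok) { restore_loc(lc, snap); return; }
    // boundaries (activation times of the two regenerated lineages included)
    double tU = lc.time[u];
    std::vector<double> bnd;
    bnd.insert(bnd.end(), e0.begin(), e0.end());
    bnd.insert(bnd.end(), e1.begin(), e1.end());
    bnd.insert(bnd.end(), s0_.begin(), s0_.end());
    bnd.insert(bnd.end(), s1_.begin(), s1_.end());
    for (int q = nsp; q < npop; q++) bnd.push_back(tau[q]);
    bnd.push_back(Tb);
    bnd.push_back(tU);
    std::sort(bnd.begin(), bnd.end());
    // regenerate u's lineage path from time[u] and the continuation of the
    // top backbone lineage from the backbone root's age Tb (the state holds
    // no path above its root, so that continuation is part of the proposal)
    double t = std::min(tU, Tb);
    int pcur = -1, pm = -1;  // -1 = not yet active
    if (t >= tU) pcur = popup(lc.pop[u], t);
    if (t >= Tb) pm = popup(lc.pop[m], t);
    std::vector<MigEv> newev, mev;
    double hth = lc.h;
    int target = -1; double tcoal = 0;
    std::vector<int> cand;
    int guard = 0;
    while (target < 0) {
      if (++guard > 100000) { restore_loc(lc, snap); return; }
      // rates
      double rmigL = 0, rmigR = 0, rcoal = 0;
      std::vector<double> mrL, mrR; std::vector<int> meL, meR;
      for (int e = 0; e < nmig; e++) {
        if (pcur >= 0 && mdst[e] == pcur && winlo(e) <= t && t < winup(e) &&
            M[e] > 0) {
          double r = 4.0 * M[e] / (theta[pcur] * hth);
          rmigL += r; mrL.push_back(r); meL.push_back(e);
        }
        if (pm >= 0 && mdst[e] == pm && winlo(e) <= t && t < winup(e) &&
            M[e] > 0) {
          double r = 4.0 * M[e] / (theta[pm] * hth);
          rmigR += r; mrR.push_back(r); meR.push_back(e);
        }
      }
      cand.clear();
      if (pcur >= 0 && t < Tb) {
        for (size_t i = 0; i < e0.size(); i++)
          if (e0[i] <= t && e1[i] > t && epop[i] == pcur) cand.push_back((int)i);
        rcoal = 2.0 * cand.size() / (theta[pcur] * hth);
      } else if (pcur >= 0 && pm >= 0) {
        rcoal = (pcur == pm) ? 2.0 / (theta[pcur] * hth) : 0.0;
      }
      double rabort = 0;
      if (pm >= 0 && t < tU) {  // top lineage vs open subtree lineages
        int ksub = 0;
        for (size_t i = 0; i < s0_.size(); i++)
          if (s0_[i] <= t && s1_[i] > t && spop_[i] == pm) ksub++;
        rabort = 2.0 * ksub / (theta[pm] * hth);
      }
      double tot = rmigL + rmigR + rcoal + rabort;
      // next structural boundary
      auto it = std::upper_bound(bnd.begin(), bnd.end(), t);
      double tb = (it == bnd.end()) ? INF : *it;
      double dt = tot > 0 ? rexp1(tot) : INF;
      if (t + dt >= tb) {
        if (tb == INF) { restore_loc(lc, snap); return; }  // cannot happen
        t = tb;
        if (pcur < 0 && t >= tU) pcur = popup(lc.pop[u], t);
        else if (pcur >= 0) pcur = popup(pcur, t);
        if (pm < 0 && t >= Tb) pm = popup(lc.pop[m], t);
        else if (pm >= 0) pm = popup(pm, t);
        continue;
      }
      t += dt;
      double uu = U() * tot;
      if (uu < rmigL) {
        double acc2 = 0; int e = meL[0];
        for (size_t i = 0; i < mrL.size(); i++) { acc2 += mrL[i]; if (uu < acc2) { e = meL[i]; break; } }
        newev.push_back({t, msrc[e]});
        pcur = msrc[e];
      } else if (uu < rmigL + rmigR) {
        double u2 = uu - rmigL, acc2 = 0; int e = meR[0];
        for (size_t i = 0; i < mrR.size(); i++) { acc2 += mrR[i]; if (u2 < acc2) { e = meR[i]; break; } }
        mev.push_back({t, msrc[e]});
        pm = msrc[e];
      } else if (uu < rmigL + rmigR + rabort) {
        restore_loc(lc, snap);  // proposal aborted: outside the move's support
        return;
      } else {
        // coalescence
        if (t < Tb) {
          int pick = std::min((int)(U() * cand.size()), (int)cand.size() - 1);
          target = enode[cand[pick]];
        } else target = m;
        tcoal = t;
      }
    }
    // reattach via recycled node p
    lc.time[p] = tcoal; lc.pop[p] = pcur;
    lc.ev[u] = newev;
    if (target == m) {
      lc.parent[m] = p; lc.parent[u] = p;
      lc.c0[p] = u; lc.c1[p] = m; lc.parent[p] = -1;
      lc.ev[m] = mev; lc.ev[p].clear();
    } else {
      int v = target, pv = lc.parent[v];
      lc.ev[p].clear();
      auto& evv = lc.ev[v];
      std::vector<MigEv> keep, up_;
      for (auto& e : evv) (e.t <= tcoal ? keep : up_).push_back(e);
      lc.ev[v] = keep; lc.ev[p] = up_;
      if (lc.c0[pv] == v) lc.c0[pv] = p; else lc.c1[pv] = p;
      lc.parent[p] = pv; lc.parent[v] = p; lc.parent[u] = p;
      lc.c0[p] = v; lc.c1[p] = u;
    }
    agg_update(lc, -1.0);
    double lg0 = logG_from(snap.A, snap.cc, snap.w, snap.b, lc.h);
    recompute_stats(lc);
    double dG = logG_loc(lc) - lg0;
    double newlogl = use_lik ? prune(lc) : 0.0;
    double lacc = beta * (newlogl - snap.logl);
    if (std::log(U()) < lacc) {
      total_logG += dG;
      total_logl += newlogl - snap.logl;
      lc.logl = newlogl;
      agg_update(lc, +1.0);
      st[5].acc++;
    } else {
      restore_loc(lc, snap);
      agg_update(lc, +1.0);
    }
  }

  void tune_one(double& step, long& att, long& acc) {
    if (att < 20) return;
    double rate = (double)acc / att;
    step *= std::exp(rate - 0.30);
    step = std::min(std::max(step, 1e-7), 20.0);
    att = acc = 0;
  }
  void tune() {
    for (int j = 0; j < npop; j++) tune_one(step_theta[j], wa_th[j], wc_th[j]);
    for (int e = 0; e < nmig; e++) tune_one(step_M[e], wa_M[e], wc_M[e]);
    for (int x = 0; x < npop - nsp; x++) tune_one(step_tau[x], wa_ta[x], wc_ta[x]);
    tune_one(step_mt, wa_mt, wc_mt);
    tune_one(step_mix, wa_mx, wc_mx);
  }

  void consistency_check(double tol, bool hard) {
    double lg = 0, ll = 0;
    for (Loc& lc : loc) {
      std::vector<double> A0 = lc.A; std::vector<int> cc0 = lc.cc, w0 = lc.w;
      std::vector<double> b0 = lc.b;
      recompute_stats(lc);
      lg += logG_loc(lc);
      if (use_lik) ll += prune(lc);
      (void)A0; (void)cc0; (void)w0; (void)b0;
    }
    if (std::abs(lg - total_logG) > tol ||
        (use_lik && std::abs(ll - total_logl) > tol)) {
      if (hard)
        stop("cache inconsistency: logG %f vs %f, logl %f vs %f",
             total_logG, lg, total_logl, ll);
    }
    total_logG = lg;
    if (use_lik) total_logl = ll;
    rebuild_aggregates();
  }
};

static Engine* build_engine(List model, List loci, List settings) {
  Engine* E = new Engine();
  E->nsp = as<int>(model["nsp"]);
  E->npop = as<int>(model["npop"]);
  E->pparent = as<std::vector<int>>(model["pparent"]);
  E->tau = as<std::vector<double>>(model["tau"]);
  E->theta = as<std::vector<double>>(model["theta"]);
  E->msrc = as<std::vector<int>>(model["msrc"]);
  E->mdst = as<std::vector<int>>(model["mdst"]);
  E->M = as<std::vector<double>>(model["M"]);
  E->nmig = (int)E->msrc.size();
  E->root = E->nsp;  // by construction
  E->k_nonroot = E->npop - E->nsp - 1;
  List pr = model["prior"];
  E->a_th = as<double>(pr["theta_shape"]); E->b_th = as<double>(pr["theta_rate"]);
  E->a_ta = as<double>(pr["tau_shape"]);  E->b_ta = as<double>(pr["tau_rate"]);
  E->a_mg = as<double>(pr["mig_shape"]);  E->b_mg = as<double>(pr["mig_rate"]);

  E->L = loci.size();
  E->loc.resize(E->L);
  for (int li = 0; li < E->L; li++) {
    List l = loci[li];
    Loc& lc = E->loc[li];
    lc.ntip = as<int>(l["ntip"]);
    lc.nnode = 2 * lc.ntip - 1;
    lc.parent = as<std::vector<int>>(l["parent"]);
    lc.time = as<std::vector<double>>(l["time"]);
    lc.pop = as<std::vector<int>>(l["pop"]);
    lc.c0.assign(lc.nnode, -1); lc.c1.assign(lc.nnode, -1);
    for (int v = 0; v < lc.nnode; v++) {
      int pa = lc.parent[v];
      if (pa >= 0) { if (lc.c0[pa] < 0) lc.c0[pa] = v; else lc.c1[pa] = v; }
    }
    lc.ev.assign(lc.nnode, {});
    IntegerVector en = l["ev_node"]; NumericVector et = l["ev_time"];
    IntegerVector eo = l["ev_to"];
    for (int i = 0; i < en.size(); i++)
      lc.ev[en[i]].push_back({et[i], eo[i]});
    for (auto& evv : lc.ev)
      std::sort(evv.begin(), evv.end(),
                [](const MigEv& a, const MigEv& b) { return a.t < b.t; });
    if (l.containsElementNamed("pat")) {
      IntegerMatrix pm = l["pat"];
      lc.npat = pm.ncol();
      lc.pat.resize((size_t)lc.npat * lc.ntip);
      for (int j = 0; j < lc.npat; j++)
        for (int i = 0; i < lc.ntip; i++)
          lc.pat[(size_t)j * lc.ntip + i] = pm(i, j);
      lc.cnt = as<std::vector<double>>(l["cnt"]);
    }
    lc.h = as<double>(l["h"]);
    lc.A.assign(E->npop, 0.0); lc.cc.assign(E->npop, 0);
    lc.w.assign(E->nmig, 0); lc.b.assign(E->nmig, 0.0);
  }

  E->use_lik = as<bool>(settings["use_likelihood"]);
  E->beta = as<double>(settings["beta"]);
  E->kernel = as<int>(settings["kernel"]);
  E->broken_hastings = as<bool>(settings["broken_hastings"]);
  E->theta_in_mixing = as<bool>(settings["theta_in_mixing"]);
  E->spr_per_locus = as<int>(settings["spr_per_locus"]);
  List stp = settings["steps"];
  int nint = E->npop - E->nsp;
  E->step_theta.assign(E->npop, as<double>(stp["theta"]));
  E->step_M.assign(std::max(E->nmig, 1), as<double>(stp["migrate"]));
  E->step_mt = as<double>(stp["migtime"]);
  E->step_tau.assign(nint, as<double>(stp["tau"]));
  E->step_mix = as<double>(stp["mixing"]);
  E->wa_th.assign(E->npop, 0); E->wc_th.assign(E->npop, 0);
  E->wa_M.assign(std::max(E->nmig, 1), 0); E->wc_M.assign(std::max(E->nmig, 1), 0);
  E->wa_ta.assign(nint, 0); E->wc_ta.assign(nint, 0);
  E->rng.seed((uint64_t)as<double>(settings["seed"]));
  return E;
}

// [[Rcpp::export]]
List cpp_run_mcmc(List model, List loci, List settings) {
  Engine* E = build_engine(model, loci, settings);
  int iterations = as<int>(settings["iterations"]);
  int burnin = as<int>(settings["burnin"]);
  int thin = as<int>(settings["thin"]);
  int check_every = as<int>(settings["check_every"]);
  bool tune_on = as<bool>(settings["tune"]);
  int tune_interval = as<int>(settings["tune_interval"]);
  LogicalVector en = settings["enable"];  // theta, migrate, migtime, tau, mixing, spr

  for (int li = 0; li < E->L; li++) {
    if (!E->check_loc(E->loc[li]))
      stop("initial gene tree at locus %d violates the model", li + 1);
    E->recompute_stats(E->loc[li]);
    E->loc[li].logl = E->prune(E->loc[li]);
  }
  E->rebuild_aggregates();
  E->total_logG = E->recompute_total_logG();
  E->total_logl = 0;
  for (const Loc& lc : E->loc) E->total_logl += lc.logl;

  int nkeep = iterations / thin;
  int ncol_tau = E->npop - E->nsp;
  int ncol = ncol_tau + E->npop + E->nmig + 4;
  NumericMatrix trace(nkeep, ncol);
  int row = 0;

  int total = burnin + iterations;
  for (int it = 0; it < total; it++) {
    if (en[0]) E->move_theta();
    if (en[1] && E->nmig > 0) E->move_migrate();
    if (en[2] && E->nmig > 0) E->move_migtime();
    if (en[3]) E->move_tau();
    if (en[5]) {
      for (int li = 0; li < E->L; li++)
        for (int r = 0; r < E->spr_per_locus; r++) E->move_spr(li);
    }
    if (en[4]) E->move_mixing();
    if (tune_on && it < burnin && (it + 1) % tune_interval == 0) E->tune();
    if (it == burnin - 1) {  // reset counters after burn-in
      for (int k = 0; k < 6; k++) { E->st[k].att = 0; E->st[k].acc = 0; }
    }
    if (check_every > 0 && (it + 1) % check_every == 0)
      E->consistency_check(1e-5, true);
    if (it >= burnin && (it - burnin + 1) % thin == 0 && row < nkeep) {
      int c = 0;
      for (int p = E->nsp; p < E->npop; p++) trace(row, c++) = E->tau[p];
      for (int p = 0; p < E->npop; p++) trace(row, c++) = E->theta[p];
      for (int e = 0; e < E->nmig; e++) trace(row, c++) = E->M[e];
      trace(row, c++) = E->total_logG;
      trace(row, c++) = E->total_logl;
      long nm = 0; double ra = 0;
      for (const Loc& lc : E->loc) {
        for (const auto& evv : lc.ev) nm += (long)evv.size();
        double mx = 0; for (double tt : lc.time) mx = std::max(mx, tt);
        ra += mx;
      }
      trace(row, c++) = (double)nm;
      trace(row, c++) = ra / std::max(1, E->L);
      row++;
    }
    if ((it & 255) == 0) Rcpp::checkUserInterrupt();
  }

  // final consistency
  double lg_cache = E->total_logG, ll_cache = E->total_logl;
  E->consistency_check(1e30, false);
  double cache_delta = std::max(std::abs(lg_cache - E->total_logG),
                                std::abs(ll_cache - E->total_logl));

  // serialize final state
  List final_loci(E->L);
  NumericVector final_logG(E->L), final_logl(E->L);
  for (int li = 0; li < E->L; li++) {
    const Loc& lc = E->loc[li];
    std::vector<int> evn; std::vector<double> evt; std::vector<int> evo;
    for (int v = 0; v < lc.nnode; v++)
      for (const auto& e : lc.ev[v]) { evn.push_back(v); evt.push_back(e.t); evo.push_back(e.to); }
    final_loci[li] = List::create(
      _["ntip"] = lc.ntip, _["parent"] = lc.parent, _["time"] = lc.time,
      _["pop"] = lc.pop, _["ev_node"] = evn, _["ev_time"] = evt,
      _["ev_to"] = evo);
    final_logG[li] = E->logG_loc(lc);
    final_logl[li] = lc.logl;
  }
  const char* mv[6] = {"theta", "migrate", "migtime", "tau", "mixing", "spr"};
  CharacterVector mnames(6); NumericVector att(6), acc(6), steps(6);
  double mean_th = 0, mean_M = 0, mean_ta = 0;
  for (double s : E->step_theta) mean_th += s / E->step_theta.size();
  for (double s : E->step_M) mean_M += s / E->step_M.size();
  for (double s : E->step_tau) mean_ta += s / E->step_tau.size();
  double stepv[6] = {mean_th, mean_M, E->step_mt, mean_ta, E->step_mix, 0.0};
  for (int k = 0; k < 6; k++) {
    mnames[k] = mv[k];
    att[k] = (double)E->st[k].att; acc[k] = (double)E->st[k].acc;
    steps[k] = stepv[k];
  }
  List out = List::create(
    _["trace"] = trace,
    _["tau"] = E->tau, _["theta"] = E->theta, _["M"] = E->M,
    _["moves"] = DataFrame::create(_["move"] = mnames, _["attempts"] = att,
                                   _["accepts"] = acc, _["step"] = steps),
    _["final_loci"] = final_loci,
    _["final_logG"] = final_logG, _["final_logl"] = final_logl,
    _["cache_delta"] = cache_delta);
  delete E;
  return out;
}

// Standalone JC69 pruning likelihood used by the R-level likelihood module.
// parent: 0-based with -1 at the root; time: node ages; pat: ntip x npat
// matrix of 0..3 codes (negative = missing); cnt: pattern multiplicities.
// [[Rcpp::export]]
double cpp_prune_jc69(IntegerVector parent, NumericVector time,
                      IntegerMatrix pat, NumericVector cnt) {
  Engine E;
  E.use_lik = true;
  Loc lc;
  lc.ntip = pat.nrow();
  lc.nnode = parent.size();
  lc.parent = as<std::vector<int>>(parent);
  lc.time = as<std::vector<double>>(time);
  lc.pop.assign(lc.nnode, 0);
  lc.ev.assign(lc.nnode, {});
  lc.c0.assign(lc.nnode, -1); lc.c1.assign(lc.nnode, -1);
  for (int v = 0; v < lc.nnode; v++) {
    int pa = lc.parent[v];
    if (pa >= 0) { if (lc.c0[pa] < 0) lc.c0[pa] = v; else lc.c1[pa] = v; }
  }
  lc.npat = pat.ncol();
  lc.pat.resize((size_t)lc.npat * lc.ntip);
  for (int j = 0; j < lc.npat; j++)
    for (int i = 0; i < lc.ntip; i++)
      lc.pat[(size_t)j * lc.ntip + i] = pat(i, j);
  lc.cnt = as<std::vector<double>>(cnt);
  lc.h = 1.0;
  return E.prune(lc);
}

// Density sufficient statistics of one gene tree under the current model:
// cross-check hook for the R implementation.
// [[Rcpp::export]]
List cpp_density_stats(List model, List locus) {
  List loci = List::create(locus);
  List settings = List::create(
    _["use_likelihood"] = false, _["beta"] = 1.0, _["kernel"] = 0,
    _["broken_hastings"] = false, _["theta_in_mixing"] = false,
    _["spr_per_locus"] = 1,
    _["steps"] = List::create(_["theta"] = 0.1, _["migrate"] = 0.1,
                              _["migtime"] = 0.001, _["tau"] = 0.001,
                              _["mixing"] = 0.1),
    _["seed"] = 1.0);
  Engine* E = build_engine(model, loci, settings);
  Loc& lc = E->loc[0];
  if (!E->check_loc(lc)) { delete E; stop("gene tree violates the model"); }
  E->recompute_stats(lc);
  List out = List::create(
    _["A"] = lc.A, _["coal_counts"] = lc.cc, _["mig_counts"] = lc.w,
    _["mig_exposure"] = lc.b, _["logG"] = E->logG_loc(lc));
  delete E;
  return out;
}
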