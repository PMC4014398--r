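// Core numerical kernels: compartmental cable integrator with discrete
// Markov channel populations (binomial algorithm), a voltage-clamp sampler
// for channel statistics, and the allosteric vesicle-release integrator.
//
// Unit conventions (consistent system, no hidden conversions):
//   potential mV, time ms, conductance uS, current nA, capacitance nF.
//   1 uS * 1 mV = 1 nA; 1 nF * 1 mV / 1 ms = 1 nA.

#include <Rcpp.h>
#include <cmath>
#include <vector>

using namespace Rcpp;

// Binomial sampler tuned for the small-count, small-probability draws that
// dominate channel stepping: waiting-time (geometric-jump) method, exact,
// falling back to R's rbinom when n*p is large. Uses R's RNG stream.
static inline int rbinom_fast(int n, double p) {
  if (n <= 0 || p <= 0.0) return 0;
  if (p >= 1.0) return n;
  if ((double)n * p > 12.0 || p > 0.35)
    return (int) R::rbinom((double)n, p);
  const double log1mp = log1p(-p);
  int count = 0;
  double i = 0.0;
  for (;;) {
    double g = std::floor(std::log(unif_rand()) / log1mp);
    i += g + 1.0;
    if (i > (double)n) break;
    ++count;
  }
  return count;
}

struct Population {
  int n_states;
  int n_trans;
  std::vector<int> from;            // 0-based state index per transition
  std::vector<int> to;
  NumericMatrix rate_tab;           // n_grid x n_trans, rates (1/ms) on V grid
  double v0, dv;                    // grid origin and spacing (mV)
  int n_grid;
  double g_single;                  // uS per open channel
  double e_rev;                     // mV
  std::vector<int> conducting;      // indices of conducting states
  std::vector< std::vector<int> > exits; // transition indices by source state
  // state: either integer counts (stochastic) or fractions (deterministic),
  // both stored as double, n_states x n_comp
  NumericMatrix state;
  std::vector<double> total;        // channels per compartment
};

static std::vector<Population> parse_pops(List pops) {
  std::vector<Population> out;
  for (int k = 0; k < pops.size(); ++k) {
    List p = pops[k];
    Population P;
    P.rate_tab = as<NumericMatrix>(p["rate_tab"]);
    P.n_grid = P.rate_tab.nrow();
    P.n_trans = P.rate_tab.ncol();
    IntegerVector fr = p["from"], to = p["to"];
    P.from.assign(fr.begin(), fr.end());
    P.to.assign(to.begin(), to.end());
    P.v0 = as<double>(p["v0"]);
    P.dv = as<double>(p["dv"]);
    P.g_single = as<double>(p["g_single"]);
    P.e_rev = as<double>(p["e_rev"]);
    IntegerVector cond = p["conducting"];
    P.conducting.assign(cond.begin(), cond.end());
    P.state = clone(as<NumericMatrix>(p["state"]));
    P.n_states = P.state.nrow();
    NumericVector tot = p["total"];
    P.total.assign(tot.begin(), tot.end());
    P.exits.assign(P.n_states, std::vector<int>());
    for (int t = 0; t < P.n_trans; ++t) P.exits[P.from[t]].push_back(t);
    out.push_back(P);
  }
  return out;
}

// linear interpolation of all transition rates of one population at V
static inline void rates_at(const Population &P, double v, double *out) {
  double x = (v - P.v0) / P.dv;
  int i0 = (int)std::floor(x);
  if (i0 < 0) i0 = 0;
  if (i0 > P.n_grid - 2) i0 = P.n_grid - 2;
  double w = x - i0;
  if (w < 0) w = 0;
  if (w > 1) w = 1;
  for (int t = 0; t < P.n_trans; ++t)
    out[t] = P.rate_tab(i0, t) * (1.0 - w) + P.rate_tab(i0 + 1, t) * w;
}

// Advance the channel populations of one compartment by dt at potential v.
// Stochastic: per source state, exits are sampled sequentially as binomials
// on the remaining occupancy (declared transition order). Deterministic:
// the exact expectation of the same update rule. If any occupied state's
// summed escape probability exceeds p_sub, the update is locally split into
// substeps so first-order transition probabilities stay valid (fast
// deactivation rates at hyperpolarized potentials would otherwise violate
// the guard even though they act on nearly empty states).
static void step_channels(Population &P, int comp, double v, double dt,
                          bool stochastic, double p_sub, double *rbuf) {
  rates_at(P, v, rbuf);
  const int ns = P.n_states;
  double max_esc = 0.0;
  for (int s = 0; s < ns; ++s) {
    if (P.state(s, comp) <= 0.0) continue;
    const std::vector<int> &ex = P.exits[s];
    double ptot = 0.0;
    for (size_t j = 0; j < ex.size(); ++j) ptot += rbuf[ex[j]] * dt;
    if (ptot > max_esc) max_esc = ptot;
  }
  int n_sub = 1;
  if (max_esc > p_sub) {
    n_sub = (int)std::ceil(max_esc / p_sub);
    if (n_sub > 1000)
      stop("channel step: escape probability %.1f per step is too large even "
           "for substepping; reduce dt (V = %.1f mV)", max_esc, v);
  }
  const double h = dt / n_sub;
  std::vector<double> delta(ns, 0.0);
  for (int sub = 0; sub < n_sub; ++sub) {
    std::fill(delta.begin(), delta.end(), 0.0);
    for (int s = 0; s < ns; ++s) {
      double navail = P.state(s, comp);
      if (navail <= 0.0) continue;
      const std::vector<int> &ex = P.exits[s];
      if (ex.empty()) continue;
      if (stochastic) {
        int rem = (int)navail;
        for (size_t j = 0; j < ex.size() && rem > 0; ++j) {
          int t = ex[j];
          int x = rbinom_fast(rem, rbuf[t] * h);
          if (x > 0) {
            delta[s] -= x;
            delta[P.to[t]] += x;
            rem -= x;
          }
        }
      } else {
        double rem = navail;
        for (size_t j = 0; j < ex.size(); ++j) {
          int t = ex[j];
          double x = rem * rbuf[t] * h;
          delta[s] -= x;
          delta[P.to[t]] += x;
          rem -= x;
        }
      }
    }
    for (int s = 0; s < ns; ++s)
      if (delta[s] != 0.0) P.state(s, comp) += delta[s];
  }
}

static inline double open_count(const Population &P, int comp) {
  double o = 0.0;
  for (size_t j = 0; j < P.conducting.size(); ++j)
    o += P.state(P.conducting[j], comp);
  return o;
}

//' @noRd
// [[Rcpp::export(name = ".cable_run")]]
List cable_run(NumericVector v_init,
               NumericVector cap_nF,
               NumericVector g_ax_uS,      // length n_comp - 1
               NumericVector g_leak_uS,
               double e_leak,
               List pops,
               NumericVector stim_nA,      // per step, injected at stim_comp
               int stim_comp,              // 0-based
               double dt, int n_steps,
               IntegerVector rec_comp,     // 0-based
               int sample_every,
               bool stochastic,
               double theta,
               double p_max) {
  const int nc = v_init.size();
  std::vector<Population> P = parse_pops(pops);
  const int npop = (int)P.size();

  std::vector<double> v(v_init.begin(), v_init.end());
  std::vector<double> a(nc), b(nc), c(nc), d(nc), cp(nc), dp(nc);
  std::vector< std::vector<double> > gpop(npop, std::vector<double>(nc));

  int max_tr = 0;
  for (int k = 0; k < npop; ++k) if (P[k].n_trans > max_tr) max_tr = P[k].n_trans;
  std::vector<double> rbuf(std::max(max_tr, 1));

  const int nrec = rec_comp.size();
  const int nsamp = n_steps / sample_every;
  NumericVector t_out(nsamp);
  NumericMatrix v_out(nsamp, nrec), ileak_out(nsamp, nrec);
  std::vector<NumericMatrix> ipop_out, open_out;
  for (int k = 0; k < npop; ++k) {
    ipop_out.push_back(NumericMatrix(nsamp, nrec));
    open_out.push_back(NumericMatrix(nsamp, nrec));
  }

  RNGScope scope;
  int isamp = 0;

  for (int step = 0; step < n_steps; ++step) {
    // conductances from current channel states
    for (int k = 0; k < npop; ++k)
      for (int i = 0; i < nc; ++i)
        gpop[k][i] = P[k].g_single * open_count(P[k], i);

    // theta-scheme (theta = 0.5: Crank-Nicolson) tridiagonal solve for V
    double istim_val = stim_nA[step];
    for (int i = 0; i < nc; ++i) {
      double gsum = g_leak_uS[i];
      double gE = g_leak_uS[i] * e_leak;
      for (int k = 0; k < npop; ++k) {
        gsum += gpop[k][i];
        gE += gpop[k][i] * P[k].e_rev;
      }
      double gl = (i > 0) ? g_ax_uS[i - 1] : 0.0;
      double gr = (i < nc - 1) ? g_ax_uS[i] : 0.0;
      // explicit part of membrane + axial current at old V
      double axial_old = 0.0;
      if (i > 0) axial_old += gl * (v[i - 1] - v[i]);
      if (i < nc - 1) axial_old += gr * (v[i + 1] - v[i]);
      double i_old = gE - gsum * v[i] + axial_old;
      a[i] = -theta * gl;
      c[i] = -theta * gr;
      b[i] = cap_nF[i] / dt + theta * (gsum + gl + gr);
      d[i] = cap_nF[i] / dt * v[i] + theta * gE + (1.0 - theta) * i_old;
      if (i == stim_comp) d[i] += istim_val;
    }
    // Thomas algorithm
    cp[0] = c[0] / b[0];
    dp[0] = d[0] / b[0];
    for (int i = 1; i < nc; ++i) {
      double m = b[i] - a[i] * cp[i - 1];
      cp[i] = c[i] / m;
      dp[i] = (d[i] - a[i] * dp[i - 1]) / m;
    }
    v[nc - 1] = dp[nc - 1];
    for (int i = nc - 2; i >= 0; --i) v[i] = dp[i] - cp[i] * v[i + 1];

    for (int i = 0; i < nc; ++i)
      if (!std::isfinite(v[i]) || std::fabs(v[i]) > 200.0)
        stop("numerical blow-up: |V| > 200 mV at compartment %d, t = %.4f ms",
             i + 1, (step + 1) * dt);

    // record with the conductances that produced this voltage step (the
    // channel update below applies to the next step)
    if ((step + 1) % sample_every == 0) {
      t_out[isamp] = (step + 1) * dt;
      for (int j = 0; j < nrec; ++j) {
        int i = rec_comp[j];
        v_out(isamp, j) = v[i];
        ileak_out(isamp, j) = g_leak_uS[i] * (v[i] - e_leak);
        for (int k = 0; k < npop; ++k) {
          double oc = open_count(P[k], i);
          open_out[k](isamp, j) = oc;
          ipop_out[k](isamp, j) = P[k].g_single * oc * (v[i] - P[k].e_rev);
        }
      }
      ++isamp;
    }

    // advance channel states at the updated potential (operator splitting)
    for (int k = 0; k < npop; ++k)
      for (int i = 0; i < nc; ++i)
        step_channels(P[k], i, v[i], dt, stochastic, p_max, rbuf.data());
  }

  List ipl(npop), opl(npop), fin(npop);
  for (int k = 0; k < npop; ++k) {
    ipl[k] = ipop_out[k];
    opl[k] = open_out[k];
    fin[k] = P[k].state;
  }
  return List::create(_["time"] = t_out, _["v"] = v_out,
                      _["i_leak"] = ileak_out, _["i_pop"] = ipl,
                      _["open"] = opl, _["final_state"] = fin);
}

//' @noRd
// [[Rcpp::export(name = ".clamp_sample")]]
IntegerMatrix clamp_sample(IntegerVector counts0,
                           IntegerVector from, IntegerVector to,
                           NumericVector rate,  // 1/ms, at the clamped V
                           double dt, int n_burn, int n_samples, int thin,
                           double p_max) {
  const int ns = counts0.size();
  const int nt = from.size();
  std::vector< std::vector<int> > exits(ns);
  for (int t = 0; t < nt; ++t) exits[from[t]].push_back(t);
  for (int s = 0; s < ns; ++s) {
    double ptot = 0.0;
    for (size_t j = 0; j < exits[s].size(); ++j) ptot += rate[exits[s][j]] * dt;
    if (ptot > p_max)
      stop("clamp_sample: escape probability %.3f exceeds %.2f; reduce dt", ptot, p_max);
  }
  std::vector<int> cnt(counts0.begin(), counts0.end());
  IntegerMatrix out(n_samples, ns);
  RNGScope scope;
  long total_steps = (long)n_burn + (long)n_samples * thin;
  int isamp = 0;
  std::vector<int> delta(ns);
  for (long step = 0; step < total_steps; ++step) {
    std::fill(delta.begin(), delta.end(), 0);
    for (int s = 0; s < ns; ++s) {
      int rem = cnt[s];
      if (rem <= 0) continue;
      for (size_t j = 0; j < exits[s].size() && rem > 0; ++j) {
        int t = exits[s][j];
        int x = rbinom_fast(rem, rate[t] * dt);
        if (x > 0) {
          delta[s] -= x;
          delta[to[t]] += x;
          rem -= x;
        }
      }
    }
    for (int s = 0; s < ns; ++s) cnt[s] += delta[s];
    if (step >= n_burn && ((step - n_burn + 1) % thin == 0)) {
      for (int s = 0; s < ns; ++s) out(isamp, s) = cnt[s];
      ++isamp;
      if (isamp >= n_samples) break;
    }
  }
  return out;
}

// Allosteric five-site release model. States n = 0..5 Ca-bound plus an
// absorbing released pool R:
//   n -> n+1 at (5-n) * kon * Ca(t)
//   n -> n-1 at n * koff * b^(n-1)
//   n -> R   at lplus * f^n
// RK4 on the (linear, time-varying) master equation; Ca(t) piecewise linear
// between samples. All rates per ms, Ca in uM.
struct RelParams { double kon, koff, b, f, lplus; double kb[6], kr[6]; };

static inline void rel_deriv(const RelParams &pp, double ca,
                             const double *x, double *dx) {
  double drel = 0.0;
  for (int n = 0; n <= 5; ++n) dx[n] = 0.0;
  for (int n = 0; n <= 5; ++n) {
    double out = 0.0;
    if (n < 5) {
      double fbind = (5 - n) * pp.kon * ca * x[n];
      dx[n + 1] += fbind;
      out += fbind;
    }
    if (n > 0) {
      double funb = pp.kb[n] * x[n];
      dx[n - 1] += funb;
      out += funb;
    }
    double frel = pp.kr[n] * x[n];
    drel += frel;
    out += frel;
    dx[n] -= out;
  }
  dx[6] = drel;
}

//' @noRd
// [[Rcpp::export(name = ".release_run")]]
List release_run(NumericMatrix ca_uM,   // n_time x n_ap
                 double dt,             // ms
                 double kon, double koff, double b, double f,
                 double lplus,          // per ms
                 bool keep_states) {
  const int nt = ca_uM.nrow();
  const int na = ca_uM.ncol();
  RelParams pp;
  pp.kon = kon; pp.koff = koff; pp.b = b; pp.f = f; pp.lplus = lplus;
  for (int n = 0; n <= 5; ++n) {
    pp.kb[n] = (n > 0) ? n * koff * std::pow(b, n - 1) : 0.0;
    pp.kr[n] = lplus * std::pow(f, n);
  }
  NumericMatrix rate(nt, na), released(nt, na);
  NumericMatrix occ = keep_states ? NumericMatrix(nt, 6 * na) : NumericMatrix(0, 0);

  double x[7], k1[7], k2[7], k3[7], k4[7], xt[7];
  for (int ap = 0; ap < na; ++ap) {
    for (int n = 0; n <= 6; ++n) x[n] = 0.0;
    x[0] = 1.0;
    for (int i = 0; i < nt; ++i) {
      double ca0 = ca_uM(i, ap);
      // record state at sample i (pre-step)
      double r = 0.0;
      for (int n = 0; n <= 5; ++n) r += pp.kr[n] * x[n];
      rate(i, ap) = r;
      released(i, ap) = x[6];
      if (keep_states)
        for (int n = 0; n <= 5; ++n) occ(i, 6 * ap + n) = x[n];
      if (i == nt - 1) break;
      double ca1 = ca_uM(i + 1, ap);
      // substep stiff intervals: keep (max rate) * h well inside the RK4
      // stability region
      double rmax = 5.0 * kon * std::max(ca0, ca1);
      for (int n = 1; n <= 5; ++n)
        rmax = std::max(rmax, pp.kb[n] + pp.kr[n]);
      int nsub = (int)std::ceil(rmax * dt / 0.5);
      if (nsub < 1) nsub = 1;
      if (nsub > 100000)
        stop("release integration too stiff even after substepping");
      double h = dt / nsub;
      for (int sub = 0; sub < nsub; ++sub) {
        double f0 = (double)sub / nsub, f1 = (double)(sub + 1) / nsub;
        double cb = ca0 + (ca1 - ca0) * f0;
        double ce = ca0 + (ca1 - ca0) * f1;
        double cm = 0.5 * (cb + ce);
        rel_deriv(pp, cb, x, k1);
        for (int n = 0; n <= 6; ++n) xt[n] = x[n] + 0.5 * h * k1[n];
        rel_deriv(pp, cm, xt, k2);
        for (int n = 0; n <= 6; ++n) xt[n] = x[n] + 0.5 * h * k2[n];
        rel_deriv(pp, cm, xt, k3);
        for (int n = 0; n <= 6; ++n) xt[n] = x[n] + h * k3[n];
        rel_deriv(pp, ce, xt, k4);
        for (int n = 0; n <= 6; ++n)
          x[n] += h / 6.0 * (k1[n] + 2.0 * k2[n] + 2.0 * k3[n] + k4[n]);
      }
    }
  }
  return List::create(_["rate"] = rate, _["released"] = released,
                      _["occupancy"] = occ);
}
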