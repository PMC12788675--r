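// Event-by-event electron transport in an infinite-ish water medium.
//
// The engine walks a primary electron and its full secondary cascade:
// exponential free flights at the local macroscopic cross section,
// channel selection proportional to the per-channel totals, screened
// Rutherford elastic deflection, excitation as a local energy drop, and
// ionization with a Lorentzian secondary-energy spectrum.  Electrons at or
// below the cutoff deposit their kinetic energy locally; electrons leaving
// the world sphere carry theirs away.  Randomness comes from a per-history
// splitmix64 stream derived from (seed, history index), so results are
// independent of execution order and bitwise reproducible.

#include <Rcpp.h>
#include <cmath>
#include <cstdint>
#include <vector>

using namespace Rcpp;

namespace {

struct Rng {
  uint64_t state;
  explicit Rng(uint64_t s) : state(s) {}
  uint64_t next_u64() {
    uint64_t z = (state += 0x9E3779B97F4A7C15ULL);
    z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
    z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
    return z ^ (z >> 31);
  }
  // uniform in (0, 1)
  double unif() {
    double u = (next_u64() >> 11) * (1.0 / 9007199254740992.0);
    return (u <= 0.0) ? 5e-324 : u;
  }
};

inline uint64_t mix_seed(uint64_t seed, uint64_t k) {
  uint64_t z = seed ^ (0x9E3779B97F4A7C15ULL * (k + 1));
  z = (z ^ (z >> 33)) * 0xFF51AFD7ED558CCDULL;
  z = (z ^ (z >> 33)) * 0xC4CEB9FE1A85EC53ULL;
  return z ^ (z >> 33);
}

struct Electron {
  double E;
  double x, y, z;
  double ux, uy, uz;
};

struct Channels {
  int n;                        // number of grid points
  std::vector<double> logE;     // log of grid energies
  std::vector<double> E;
  // per channel: sigma values and log(sigma) (NaN where sigma == 0)
  std::vector<std::vector<double>> sig, logsig;
  std::vector<int> kind;        // 0 ionization, 1 excitation, 2 elastic
  std::vector<double> trans;    // binding/excitation energy (eV), NaN elastic
  bool loglog;
};

// interpolated sigma for channel c at energy Ek (clamped to the grid span;
// inelastic channels are zero at/below threshold by construction of the
// tabulated values)
double sigma_at(const Channels& ch, int c, double Ek, int i) {
  const std::vector<double>& s = ch.sig[c];
  double lo = s[i], hi = s[i + 1];
  if (ch.loglog && lo > 0.0 && hi > 0.0) {
    double t = (std::log(Ek) - ch.logE[i]) / (ch.logE[i + 1] - ch.logE[i]);
    return std::exp(ch.logsig[c][i] + t * (ch.logsig[c][i + 1] - ch.logsig[c][i]));
  }
  double t = (Ek - ch.E[i]) / (ch.E[i + 1] - ch.E[i]);
  return lo + t * (hi - lo);
}

int grid_index(const Channels& ch, double Ek) {
  // binary search: largest i with E[i] <= Ek, clamped to [0, n-2]
  if (Ek <= ch.E[0]) return 0;
  if (Ek >= ch.E[ch.n - 1]) return ch.n - 2;
  int lo = 0, hi = ch.n - 1;
  while (hi - lo > 1) {
    int mid = (lo + hi) / 2;
    if (ch.E[mid] <= Ek) lo = mid; else hi = mid;
  }
  return lo;
}

// screening parameter of the screened-Rutherford elastic model
inline double eta_of(double E, double eta_scale, double z23) {
  double tau = E / 511000.0;
  return eta_scale * z23 / (tau * (tau + 2.0));
}

// sample cos(theta) from P(mu) propto (1 + 2 eta - mu)^-2 on [-1, 1]
inline double sample_mu(double eta, double u) {
  double a = 1.0 + 2.0 * eta;
  double inv = 1.0 / (a + 1.0) + u * (1.0 / (a - 1.0) - 1.0 / (a + 1.0));
  return a - 1.0 / inv;
}

inline void rotate(Electron& el, double mu, double phi) {
  double st = std::sqrt(std::max(0.0, 1.0 - mu * mu));
  double cp = std::cos(phi), sp = std::sin(phi);
  double ux = el.ux, uy = el.uy, uz = el.uz;
  if (std::fabs(uz) > 0.999999999) {
    el.ux = st * cp;
    el.uy = st * sp;
    el.uz = mu * (uz > 0 ? 1.0 : -1.0);
  } else {
    double den = std::sqrt(1.0 - uz * uz);
    el.ux = mu * ux + st * (ux * uz * cp - uy * sp) / den;
    el.uy = mu * uy + st * (uy * uz * cp + ux * sp) / den;
    el.uz = mu * uz - st * den * cp;
  }
  // renormalize to keep |u| = 1 against drift
  double nrm = std::sqrt(el.ux * el.ux + el.uy * el.uy + el.uz * el.uz);
  el.ux /= nrm; el.uy /= nrm; el.uz /= nrm;
}

}  // namespace

// [[Rcpp::export(name = ".transport_engine")]]
List transport_engine(double energy0, int n_histories,
                      NumericVector grid, NumericMatrix sigma,
                      IntegerVector kind, NumericVector trans,
                      double number_density, double cutoff,
                      double world_radius, double sphere_radius,
                      int seed, bool isotropic_start,
                      double epsilon0, double eta_scale, double z_eff,
                      bool loglog, bool keep_events,
                      double max_events_per_history = 5e6) {
  const int nch = sigma.ncol();
  if (nch != 11) stop("sigma must have 11 channel columns");
  Channels ch;
  ch.n = grid.size();
  ch.loglog = loglog;
  ch.E.assign(grid.begin(), grid.end());
  ch.logE.resize(ch.n);
  for (int i = 0; i < ch.n; ++i) ch.logE[i] = std::log(grid[i]);
  ch.sig.resize(nch);
  ch.logsig.resize(nch);
  for (int c = 0; c < nch; ++c) {
    ch.sig[c].resize(ch.n);
    ch.logsig[c].resize(ch.n);
    for (int i = 0; i < ch.n; ++i) {
      ch.sig[c][i] = sigma(i, c);
      ch.logsig[c][i] = sigma(i, c) > 0 ? std::log(sigma(i, c)) : 0.0;
    }
  }
  ch.kind.assign(kind.begin(), kind.end());
  ch.trans.assign(trans.begin(), trans.end());

  const double z23 = std::pow(z_eff, 2.0 / 3.0);
  const double world2 = world_radius * world_radius;
  const double sph2 = sphere_radius > 0 ? sphere_radius * sphere_radius : -1.0;

  IntegerVector nu_out(n_histories), first_ch(n_histories), nev_out(n_histories);
  NumericVector dep_out(n_histories), term_out(n_histories), esc_out(n_histories);
  IntegerVector truncated(n_histories);

  // optional event log (only sensible for small runs)
  std::vector<int> ev_hist, ev_idx, ev_chan;
  std::vector<double> ev_x, ev_y, ev_z, ev_dep, ev_sec, ev_Epre;

  std::vector<double> sig_now(nch);

  for (int h = 0; h < n_histories; ++h) {
    Rng rng(mix_seed((uint64_t)seed, (uint64_t)h));
    double deposited = 0.0, terminated = 0.0, escaped = 0.0;
    int nu = 0, nev = 0, first = 0;
    bool trunc = false;

    std::vector<Electron> stack;
    Electron prim;
    prim.E = energy0;
    prim.x = prim.y = prim.z = 0.0;
    if (isotropic_start) {
      double mu = 2.0 * rng.unif() - 1.0;
      double phi = 2.0 * M_PI * rng.unif();
      double st = std::sqrt(1.0 - mu * mu);
      prim.ux = st * std::cos(phi); prim.uy = st * std::sin(phi); prim.uz = mu;
    } else {
      prim.ux = 0.0; prim.uy = 0.0; prim.uz = 1.0;
    }
    if (prim.E <= cutoff) {
      terminated += prim.E;
    } else {
      stack.push_back(prim);
    }

    while (!stack.empty()) {
      Electron el = stack.back();
      stack.pop_back();
      while (true) {
        if (nev >= max_events_per_history) {
          terminated += el.E;  // safety valve; reported via 'truncated'
          trunc = true;
          break;
        }
        int gi = grid_index(ch, el.E);
        double tot = 0.0;
        for (int c = 0; c < nch; ++c) {
          double s = 0.0;
          if (ch.kind[c] == 2 || el.E > ch.trans[c]) {
            s = sigma_at(ch, c, el.E, gi);
            if (s < 0.0) s = 0.0;
            if (ch.kind[c] != 2 && el.E < ch.E[0]) s = 0.0;
          }
          sig_now[c] = s;
          tot += s;
        }
        if (tot <= 0.0) {
          // medium transparent to this electron: absorb locally
          terminated += el.E;
          break;
        }
        double Sigma = number_density * tot;
        double step = -std::log(rng.unif()) / Sigma;
        el.x += step * el.ux; el.y += step * el.uy; el.z += step * el.uz;
        double r2 = el.x * el.x + el.y * el.y + el.z * el.z;
        if (r2 > world2) {
          escaped += el.E;
          break;
        }
        // channel selection
        double u = rng.unif() * tot, acc = 0.0;
        int c = nch - 1;
        for (int j = 0; j < nch; ++j) {
          acc += sig_now[j];
          if (u <= acc) { c = j; break; }
        }
        ++nev;
        if (first == 0) first = c + 1;
        double dep = 0.0, sec_energy = NA_REAL;

        if (ch.kind[c] == 2) {                       // elastic
          double mu = sample_mu(eta_of(el.E, eta_scale, z23), rng.unif());
          rotate(el, mu, 2.0 * M_PI * rng.unif());
        } else if (ch.kind[c] == 1) {                // excitation
          dep = ch.trans[c];
          el.E -= dep;
          deposited += dep;
        } else {                                     // ionization
          double B = ch.trans[c];
          double emax = 0.5 * (el.E - B);
          double eps = epsilon0 * std::tan(rng.unif() * std::atan(emax / epsilon0));
          dep = B;
          deposited += B;
          sec_energy = eps;
          if (sph2 > 0.0 && r2 < sph2) ++nu;
          el.E = el.E - B - eps;
          if (eps > cutoff) {
            Electron sec;
            sec.E = eps;
            sec.x = el.x; sec.y = el.y; sec.z = el.z;
            double mu = 2.0 * rng.unif() - 1.0;
            double phi = 2.0 * M_PI * rng.unif();
            double st = std::sqrt(1.0 - mu * mu);
            sec.ux = st * std::cos(phi); sec.uy = st * std::sin(phi); sec.uz = mu;
            stack.push_back(sec);
          } else {
            terminated += eps;
          }
        }
        if (keep_events) {
          ev_hist.push_back(h + 1); ev_idx.push_back(nev); ev_chan.push_back(c + 1);
          ev_x.push_back(el.x); ev_y.push_back(el.y); ev_z.push_back(el.z);
          ev_dep.push_back(dep); ev_sec.push_back(sec_energy);
        }
        if (ch.kind[c] != 2 && el.E <= cutoff) {
          terminated += el.E;
          break;
        }
      }
    }
    nu_out[h] = nu;
    first_ch[h] = first;
    nev_out[h] = nev;
    dep_out[h] = deposited;
    term_out[h] = terminated;
    esc_out[h] = escaped;
    truncated[h] = trunc ? 1 : 0;
  }

  List out = List::create(
    _["nu"] = nu_out,
    _["first_channel"] = first_ch,
    _["n_events"] = nev_out,
    _["deposited"] = dep_out,
    _["terminated"] = term_out,
    _["escaped"] = esc_out,
    _["truncated"] = truncated);
  if (keep_events) {
    out["events"] = DataFrame::create(
      _["history"] = wrap(ev_hist),
      _["event"] = wrap(ev_idx),
      _["channel"] = wrap(ev_chan),
      _["x"] = wrap(ev_x), _["y"] = wrap(ev_y), _["z"] = wrap(ev_z),
      _["deposit"] = wrap(ev_dep),
      _["secondary_energy"] = wrap(ev_sec));
  }
  return out;
}
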