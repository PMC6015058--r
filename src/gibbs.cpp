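// Blocked Gibbs sweep for the two-HDP Gaussian mixture over plate readouts.
//
// Layout conventions (shared with the R wrappers in R/sampler.R):
//   channel index c: 0 = inactive, 1 = active
//   lab[i] in 1..H      local cluster of well i within its channel
//   map[(m, c, h)]      global atom k in 1..K for local cluster h of plate m,
//                       stored as an R array of dim (M, 2, H):
//                       linear index m + M*(c + 2*h)
//   v same layout       local beta sticks, v[.., H-1] == 1
//   u, mu, s2: K x 2    global sticks / atom means / atom variances
//
// All randomness comes from R's RNG (RNGScope), so set.seed() on the R
// side reproduces sweeps bit-exactly.

#include <Rcpp.h>
#include <cmath>
#include <vector>

using namespace Rcpp;

static const double LOG2PI = 1.8378770664093454836;

static inline double log_dnorm(double z, double mu, double s2) {
  double d = z - mu;
  return -0.5 * (LOG2PI + std::log(s2) + d * d / s2);
}

// stick-breaking: w[l] = v[l] * prod_{j<l} (1 - v[j]); closed by w[L-1]
static void sticks_to_weights(const std::vector<double>& v,
                              std::vector<double>& w) {
  const int L = (int)v.size();
  double rem = 1.0;
  for (int l = 0; l < L - 1; ++l) {
    w[l] = v[l] * rem;
    rem *= (1.0 - v[l]);
  }
  w[L - 1] = rem;
}

// categorical draw from unnormalized log-probabilities, 0-based
static int sample_cat_log(const std::vector<double>& lp) {
  const int L = (int)lp.size();
  double mx = lp[0];
  for (int l = 1; l < L; ++l) if (lp[l] > mx) mx = lp[l];
  double tot = 0.0;
  std::vector<double> p(L);
  for (int l = 0; l < L; ++l) {
    p[l] = (lp[l] - mx > -40.0) ? std::exp(lp[l] - mx) : 0.0;
    tot += p[l];
  }
  double uu = unif_rand() * tot, acc = 0.0;
  for (int l = 0; l < L; ++l) {
    acc += p[l];
    if (uu <= acc) return l;
  }
  return L - 1;
}

static inline double rbeta_safe(double s1, double s2) {
  double x = R::rbeta(s1, s2);
  if (x < 1e-12) x = 1e-12;
  if (x > 1.0 - 1e-12) x = 1.0 - 1e-12;
  return x;
}

// [[Rcpp::export]]
List gibbs_sweep_cpp(NumericVector z, IntegerVector plate0, int M,
                     double pi_, IntegerVector b, IntegerVector lab,
                     IntegerVector map, NumericVector v,
                     NumericMatrix u, NumericMatrix mu, NumericMatrix s2,
                     NumericVector alpha, NumericVector tau, List hyper) {
  RNGScope scope;
  const int n = z.size();
  const int K = u.nrow();
  const int H = (int)(v.size() / (2 * M));

  const double a_pi = hyper["a_pi"], b_pi = hyper["b_pi"];
  const double a_alpha = hyper["a_alpha"], b_alpha = hyper["b_alpha"];
  const double a_tau = hyper["a_tau"], b_tau = hyper["b_tau"];
  const double ig_a = hyper["a"], ig_b = hyper["b"];
  const double mu00 = hyper["mu00"], mu10 = hyper["mu10"];

  IntegerVector bN = clone(b), labN = clone(lab), mapN = clone(map);
  NumericVector vN = clone(v);
  NumericMatrix uN = clone(u), muN = clone(mu), s2N = clone(s2);
  NumericVector alphaN = clone(alpha), tauN = clone(tau);

  auto MAPIDX = [&](int m, int c, int h) { return m + M * (c + 2 * h); };

  // local weights (per plate, channel) and their logs, plus the atom
  // parameters each local cluster currently points to. For the per-well
  // loops the Gaussian is folded into cl0 + cl1 * (z - mu)^2 with the
  // log terms hoisted out here.
  std::vector<double> lw(2L * M * H), amu(2L * M * H), as2(2L * M * H),
      cl0(2L * M * H), cl1(2L * M * H);
  {
    std::vector<double> vb(H), wb(H);
    for (int m = 0; m < M; ++m) {
      for (int c = 0; c < 2; ++c) {
        for (int h = 0; h < H; ++h) vb[h] = vN[MAPIDX(m, c, h)];
        sticks_to_weights(vb, wb);
        for (int h = 0; h < H; ++h) {
          int idx = MAPIDX(m, c, h);
          lw[idx] = (wb[h] > 0.0) ? std::log(wb[h]) : R_NegInf;
          int k = mapN[idx] - 1;
          amu[idx] = muN(k, c);
          as2[idx] = s2N(k, c);
          cl0[idx] = (lw[idx] == R_NegInf)
                       ? R_NegInf
                       : lw[idx] - 0.5 * (LOG2PI + std::log(as2[idx]));
          cl1[idx] = -0.5 / as2[idx];
        }
      }
    }
  }

  // global log-weights per channel
  std::vector<double> lglob(2L * K);
  {
    std::vector<double> ub(K), wb(K);
    for (int c = 0; c < 2; ++c) {
      for (int k = 0; k < K; ++k) ub[k] = uN(k, c);
      sticks_to_weights(ub, wb);
      for (int k = 0; k < K; ++k)
        lglob[c * K + k] = (wb[k] > 0.0) ? std::log(wb[k]) : R_NegInf;
    }
  }

  const double lpi1 = std::log(pi_), lpi0 = std::log1p(-pi_);

  // ---- step 1: activity indicators b_mi ------------------------------
  NumericVector pact(n);  // conditional P(b_i = 1 | rest), for summaries
  for (int i = 0; i < n; ++i) {
    const int m = plate0[i];
    double lf[2];
    for (int c = 0; c < 2; ++c) {
      double mx = R_NegInf;
      double terms[64];  // H <= 64 enforced on the R side
      for (int h = 0; h < H; ++h) {
        int idx = MAPIDX(m, c, h);
        double d = z[i] - amu[idx];
        double t = cl0[idx] + cl1[idx] * d * d;
        terms[h] = t;
        if (t > mx) mx = t;
      }
      double s = 0.0;
      for (int h = 0; h < H; ++h)
        if (terms[h] - mx > -40.0) s += std::exp(terms[h] - mx);
      lf[c] = mx + std::log(s);
    }
    double t1 = lpi1 + lf[1], t0 = lpi0 + lf[0];
    double p1 = 1.0 / (1.0 + std::exp(t0 - t1));
    pact[i] = p1;
    bN[i] = (unif_rand() < p1) ? 1 : 0;
  }

  // ---- step 2: local cluster labels ----------------------------------
  {
    std::vector<double> lp(H);
    for (int i = 0; i < n; ++i) {
      const int m = plate0[i], c = bN[i];
      for (int h = 0; h < H; ++h) {
        int idx = MAPIDX(m, c, h);
        double d = z[i] - amu[idx];
        lp[h] = cl0[idx] + cl1[idx] * d * d;
      }
      labN[i] = sample_cat_log(lp) + 1;
    }
  }

  // sufficient statistics per local cluster (m, c, h)
  std::vector<double> cnt(2L * M * H, 0.0), sz(2L * M * H, 0.0),
      szz(2L * M * H, 0.0);
  for (int i = 0; i < n; ++i) {
    int idx = MAPIDX(plate0[i], bN[i], labN[i] - 1);
    cnt[idx] += 1.0;
    sz[idx] += z[i];
    szz[idx] += z[i] * z[i];
  }

  // ---- step 3: local-to-global maps ----------------------------------
  {
    std::vector<double> lp(K), lnc(2L * K), inv(2L * K);
    for (int c = 0; c < 2; ++c) {
      for (int k = 0; k < K; ++k) {
        lnc[c * K + k] = -0.5 * (LOG2PI + std::log(s2N(k, c)));
        inv[c * K + k] = 0.5 / s2N(k, c);
      }
    }
    for (int m = 0; m < M; ++m) {
      for (int c = 0; c < 2; ++c) {
        for (int h = 0; h < H; ++h) {
          int idx = MAPIDX(m, c, h);
          double nc = cnt[idx], s1 = sz[idx], s2sum = szz[idx];
          for (int k = 0; k < K; ++k) {
            double lpk = lglob[c * K + k];
            if (lpk != R_NegInf && nc > 0.0) {
              double mk = muN(k, c);
              lpk += nc * lnc[c * K + k] -
                     inv[c * K + k] * (s2sum - 2.0 * mk * s1 + nc * mk * mk);
            }
            lp[k] = lpk;
          }
          mapN[idx] = sample_cat_log(lp) + 1;
        }
      }
    }
  }

  // ---- step 4: local and global sticks -------------------------------
  for (int m = 0; m < M; ++m) {
    for (int c = 0; c < 2; ++c) {
      std::vector<double> nh(H);
      for (int h = 0; h < H; ++h) nh[h] = cnt[MAPIDX(m, c, h)];
      double tail = 0.0;  // sum of counts strictly after current stick
      for (int h = H - 1; h >= 1; --h) tail += nh[h];
      for (int h = 0; h < H - 1; ++h) {
        vN[MAPIDX(m, c, h)] = rbeta_safe(1.0 + nh[h], alphaN[c] + tail);
        tail -= nh[h + 1];
      }
      vN[MAPIDX(m, c, H - 1)] = 1.0;
    }
  }
  for (int c = 0; c < 2; ++c) {
    std::vector<double> gk(K, 0.0);
    for (int m = 0; m < M; ++m)
      for (int h = 0; h < H; ++h) gk[mapN[MAPIDX(m, c, h)] - 1] += 1.0;
    double tail = 0.0;
    for (int k = K - 1; k >= 1; --k) tail += gk[k];
    for (int k = 0; k < K - 1; ++k) {
      uN(k, c) = rbeta_safe(1.0 + gk[k], tauN[c] + tail);
      tail -= gk[k + 1];
    }
    uN(K - 1, c) = 1.0;
  }

  // ---- step 5: atoms (Normal-inverse-gamma conjugate update) ---------
  {
    std::vector<double> gn(2L * K, 0.0), gs1(2L * K, 0.0), gs2(2L * K, 0.0);
    for (int i = 0; i < n; ++i) {
      int c = bN[i];
      int k = mapN[MAPIDX(plate0[i], c, labN[i] - 1)] - 1;
      gn[c * K + k] += 1.0;
      gs1[c * K + k] += z[i];
      gs2[c * K + k] += z[i] * z[i];
    }
    for (int c = 0; c < 2; ++c) {
      double mu0 = (c == 1) ? mu10 : mu00;
      for (int k = 0; k < K; ++k) {
        double nk = gn[c * K + k];
        double sig2, muk;
        if (nk == 0.0) {
          sig2 = 1.0 / R::rgamma(ig_a, 1.0 / ig_b);
          muk = R::rnorm(mu0, std::sqrt(sig2));
        } else {
          double zbar = gs1[c * K + k] / nk;
          double ss = gs2[c * K + k] - nk * zbar * zbar;
          if (ss < 0.0) ss = 0.0;
          double kn = 1.0 + nk;
          double mun = (mu0 + gs1[c * K + k]) / kn;
          double an = ig_a + 0.5 * nk;
          double bn = ig_b + 0.5 * ss +
                      0.5 * nk * (zbar - mu0) * (zbar - mu0) / kn;
          sig2 = 1.0 / R::rgamma(an, 1.0 / bn);
          muk = R::rnorm(mun, std::sqrt(sig2 / kn));
        }
        if (sig2 < 1e-12) sig2 = 1e-12;
        if (!R_FINITE(sig2)) sig2 = 1e12;
        s2N(k, c) = sig2;
        muN(k, c) = muk;
      }
    }
  }

  // ---- step 6: mixing proportion pi ----------------------------------
  double n1 = 0.0;
  for (int i = 0; i < n; ++i) n1 += bN[i];
  double piN = rbeta_safe(a_pi + n1, b_pi + (double)n - n1);

  // ---- step 7: DP concentrations -------------------------------------
  for (int c = 0; c < 2; ++c) {
    double slog = 0.0;
    for (int m = 0; m < M; ++m)
      for (int h = 0; h < H - 1; ++h) slog += std::log1p(-vN[MAPIDX(m, c, h)]);
    alphaN[c] = R::rgamma(a_alpha + (double)M * (H - 1),
                          1.0 / (b_alpha - slog));
    slog = 0.0;
    for (int k = 0; k < K - 1; ++k) slog += std::log1p(-uN(k, c));
    tauN[c] = R::rgamma(a_tau + (double)(K - 1), 1.0 / (b_tau - slog));
  }

  return List::create(_["pi"] = piN, _["b"] = bN, _["lab"] = labN,
                      _["map"] = mapN, _["v"] = vN, _["u"] = uN,
                      _["mu"] = muN, _["s2"] = s2N, _["alpha"] = alphaN,
                      _["tau"] = tauN, _["p_active"] = pact);
}
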