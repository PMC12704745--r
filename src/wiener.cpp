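#include <Rcpp.h>
using namespace Rcpp;

// First-passage-time density of a Wiener diffusion with absorbing boundaries
// at 0 and a, start point w*a, drift v, diffusion scale s = 1.
// Series representations evaluated in normalised time tt = t / a^2 with the
// small-time / large-time switch chosen per evaluation so that the truncation
// error of the infinite sum is below `err`.

static double fpt_lower_norm(double tt, double w, double err) {
  // density (normalised time) at the lower boundary for a zero-drift process
  if (tt <= 0.0) return 0.0;

  // number of terms needed by each representation
  double ks = 2.0, kl = 1.0;
  if (2.0 * err * std::sqrt(2.0 * M_PI * tt) < 1.0) {
    ks = 2.0 + std::sqrt(-2.0 * tt * std::log(2.0 * err * std::sqrt(2.0 * M_PI * tt)));
    ks = std::max(ks, std::sqrt(tt) + 1.0);
  }
  if (M_PI * tt * err < 1.0) {
    kl = std::sqrt(-2.0 * std::log(M_PI * tt * err) / (M_PI * M_PI * tt));
    kl = std::max(kl, 1.0 / (M_PI * std::sqrt(tt)));
  }

  double f = 0.0;
  if (ks < kl) { // small-time expansion
    int K = (int)std::ceil(ks);
    int lo = -((K - 1) / 2), hi = (K - 1) / 2 + ((K - 1) % 2);
    for (int k = lo; k <= hi; ++k) {
      double u = w + 2.0 * k;
      f += u * std::exp(-u * u / (2.0 * tt));
    }
    f /= std::sqrt(2.0 * M_PI * tt * tt * tt);
  } else {       // large-time expansion
    int K = (int)std::ceil(kl);
    for (int k = 1; k <= K; ++k) {
      f += k * std::exp(-k * k * M_PI * M_PI * tt / 2.0) * std::sin(k * M_PI * w);
    }
    f *= M_PI;
  }
  return f;
}

static double dwiener_one(double t, double a, double v, double w, double t0,
                          bool upper, double err) {
  double td = t - t0;
  if (td <= 0.0 || a <= 0.0 || w <= 0.0 || w >= 1.0) return 0.0;
  double vv = v, ww = w;
  if (upper) { vv = -v; ww = 1.0 - w; } // reflect: upper density = lower of mirrored process
  double tt = td / (a * a);
  double f0 = fpt_lower_norm(tt, ww, err);
  double f = f0 * std::exp(-vv * a * ww - vv * vv * td / 2.0) / (a * a);
  return (f > 0.0 && R_finite(f)) ? f : 0.0;
}

//' @noRd
// [[Rcpp::export(name = ".dwiener_cpp")]]
NumericVector dwiener_cpp(NumericVector t, double a, double v, double w,
                          double t0, bool upper, double err = 1e-7) {
  int n = t.size();
  NumericVector out(n);
  for (int i = 0; i < n; ++i) out[i] = dwiener_one(t[i], a, v, w, t0, upper, err);
  return out;
}

// Negative log-likelihood of accuracy-coded diffusion data: trial i has
// decision time rt[i], hit the upper boundary iff upper[i] == 1, and drift
// v[i] (signed so that the upper boundary is drift-congruent).
// [[Rcpp::export(name = ".wiener_nll_cpp")]]
double wiener_nll_cpp(NumericVector rt, IntegerVector upper, NumericVector v,
                      double a, double w, double t0, double err = 1e-7) {
  int n = rt.size();
  double nll = 0.0;
  for (int i = 0; i < n; ++i) {
    double f = dwiener_one(rt[i], a, v[i], w, t0, upper[i] == 1, err);
    // floor underflowing / out-of-support densities so optimisers see a
    // finite (heavily penalised) objective rather than Inf
    nll -= std::log(std::max(f, 1e-300));
  }
  return nll;
}

// Euler-Maruyama simulation of the decision stage: one diffusion per trial
// with per-trial drift, boundaries {0, a}, start w*a, step dt, diffusion
// scale 1. Returns first-passage time (excluding t0), boundary indicator and
// a censoring flag for paths that have not been absorbed by max_t.
// [[Rcpp::export(name = ".euler_ddm_cpp")]]
NumericMatrix euler_ddm_cpp(NumericVector v, double a, double w, double dt,
                            double max_t) {
  int n = v.size();
  NumericMatrix out(n, 3); // fpt, upper, censored
  double sdt = std::sqrt(dt);
  int max_steps = (int)std::ceil(max_t / dt);
  for (int i = 0; i < n; ++i) {
    double x = w * a;
    int step = 0;
    bool absorbed = false;
    while (step < max_steps) {
      x += v[i] * dt + sdt * norm_rand();
      ++step;
      if (x >= a) { out(i, 0) = step * dt; out(i, 1) = 1.0; absorbed = true; break; }
      if (x <= 0.0) { out(i, 0) = step * dt; out(i, 1) = 0.0; absorbed = true; break; }
    }
    if (!absorbed) {
      out(i, 0) = max_t;
      out(i, 1) = (x >= w * a) ? 1.0 : 0.0;
      out(i, 2) = 1.0;
    }
  }
  return out;
}
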