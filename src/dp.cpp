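#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Closed-form marginal likelihood of one segment under the conjugate
// Normal(theta; mu0, sigma0^2) prior on the segment level and
// Normal(x_t; theta, sigma^2) probe noise:
//   log m(i..j) = -(l/2) log(2 pi sigma^2)
//                 + (1/2) log(sigma^2 / (sigma^2 + l sigma0^2))
//                 - SS / (2 sigma^2)
//                 - l (xbar - mu0)^2 / (2 (sigma^2 + l sigma0^2))
// with l = j-i+1, xbar the segment mean, SS the within-segment sum of squares.
// Prefix sums make each query O(1).
struct MarginalCache {
  int n;
  double mu0, sigma2, sigma02;
  std::vector<double> cs, css; // cs[j] = sum_{t<=j} x_t (1-based)
  double lc, inv2s2;
  std::vector<double> halflog, inv2den; // per segment length l

  MarginalCache(const NumericVector &x, double mu0_, double s2, double s02)
      : n(x.size()), mu0(mu0_), sigma2(s2), sigma02(s02), cs(n + 1, 0.0),
        css(n + 1, 0.0), halflog(n + 1, 0.0), inv2den(n + 1, 0.0) {
    for (int t = 1; t <= n; ++t) {
      cs[t] = cs[t - 1] + x[t - 1];
      css[t] = css[t - 1] + x[t - 1] * x[t - 1];
    }
    lc = -0.5 * std::log(2.0 * M_PI * sigma2);
    inv2s2 = 1.0 / (2.0 * sigma2);
    for (int l = 1; l <= n; ++l) {
      double denom = sigma2 + l * sigma02;
      halflog[l] = 0.5 * std::log(sigma2 / denom);
      inv2den[l] = 1.0 / (2.0 * denom);
    }
  }

  // 1-based inclusive probe indices
  double logm(int i, int j) const {
    int l = j - i + 1;
    double sx = cs[j] - cs[i - 1];
    double sxx = css[j] - css[i - 1];
    double xbar = sx / l;
    double ss = sxx - l * xbar * xbar;
    if (ss < 0) ss = 0; // guard numerical cancellation
    double d = xbar - mu0;
    return lc * l + halflog[l] - ss * inv2s2 - l * d * d * inv2den[l];
  }

  // posterior mean of the segment level given its data
  double postmean(int i, int j) const {
    int l = j - i + 1;
    double xbar = (cs[j] - cs[i - 1]) / l;
    return (sigma02 * l * xbar + sigma2 * mu0) / (sigma2 + l * sigma02);
  }
};

// [[Rcpp::export]]
NumericVector marginal_loglik_cpp(NumericVector x, IntegerVector i,
                                  IntegerVector j, double mu0, double sigma2,
                                  double sigma02) {
  MarginalCache mc(x, mu0, sigma2, sigma02);
  int m = i.size();
  NumericVector out(m);
  for (int q = 0; q < m; ++q) {
    if (i[q] < 1 || j[q] > mc.n || i[q] > j[q])
      stop("segment indices out of range");
    out[q] = mc.logm(i[q], j[q]);
  }
  return out;
}

// log S_k(j): sum over placements of k-1 internal breakpoints in x[1..j] of
// the product of per-segment marginals.  Row k, column j (both 1-based).
// S_1(j) = m(1..j); S_k(j) = sum_{v=k-1}^{j-1} S_{k-1}(v) m(v+1..j).
// `forbidden` (length n-1) excludes gap v as a segment boundary, so the
// table restricted to forbidden = W sums only segmentations avoiding W.
// [[Rcpp::export]]
NumericMatrix dp_table_cpp(NumericVector x, double mu0, double sigma2,
                           double sigma02, int kmax,
                           LogicalVector forbidden) {
  int n = x.size();
  if (kmax < 1 || kmax > n)
    stop("kmax must be in [1, n]");
  if (forbidden.size() != n - 1)
    stop("forbidden must have length n - 1");
  MarginalCache mc(x, mu0, sigma2, sigma02);
  NumericMatrix logS(kmax, n);
  std::fill(logS.begin(), logS.end(), R_NegInf);
  for (int j = 1; j <= n; ++j)
    logS(0, j - 1) = mc.logm(1, j);
  std::vector<double> terms;
  for (int k = 2; k <= kmax; ++k) {
    for (int j = k; j <= n; ++j) {
      // log-sum-exp over v = k-1 .. j-1, two-pass for speed/stability
      double mx = R_NegInf;
      terms.clear();
      for (int v = k - 1; v <= j - 1; ++v) {
        if (forbidden[v - 1]) continue;
        double t = logS(k - 2, v - 1) + mc.logm(v + 1, j);
        terms.push_back(t);
        if (t > mx) mx = t;
      }
      if (mx == R_NegInf) {
        logS(k - 1, j - 1) = R_NegInf;
      } else {
        double acc = 0.0;
        double lo = mx - 37.0; // below this exp() cannot move the sum
        for (double t : terms)
          if (t > lo) acc += std::exp(t - mx);
        logS(k - 1, j - 1) = mx + std::log(acc);
      }
    }
  }
  return logS;
}

// Exact independent draws from P(A | X): draw K from its posterior, then walk
// the DP table backwards, drawing each previous boundary v with probability
// proportional to S_{q-1}(v) m(v+1..w).  Uses R's RNG so set.seed() applies.
// Returns per draw the sorted internal gap indices (gap g = boundary between
// probes g and g+1) and the posterior-mean level of each segment.
// [[Rcpp::export]]
List sample_sequences_cpp(NumericVector x, NumericMatrix logS,
                          NumericVector post_k, double mu0, double sigma2,
                          double sigma02, int n_samples) {
  int n = x.size();
  int kmax = logS.nrow();
  MarginalCache mc(x, mu0, sigma2, sigma02);
  List gaps(n_samples), levels(n_samples);
  std::vector<double> cum(kmax);
  double c = 0.0;
  for (int k = 0; k < kmax; ++k) {
    c += post_k[k];
    cum[k] = c;
  }
  std::vector<double> w_(n), lv;
  std::vector<int> gp;
  for (int s = 0; s < n_samples; ++s) {
    double u = unif_rand() * cum[kmax - 1];
    int K = kmax;
    for (int k = 0; k < kmax; ++k) {
      if (u <= cum[k]) { K = k + 1; break; }
    }
    gp.clear();
    lv.clear();
    int w = n;
    for (int q = K; q >= 2; --q) {
      // draw previous boundary v in {q-1, ..., w-1}
      double mx = R_NegInf;
      for (int v = q - 1; v <= w - 1; ++v) {
        double t = logS(q - 2, v - 1) + mc.logm(v + 1, w);
        w_[v] = t;
        if (t > mx) mx = t;
      }
      double tot = 0.0;
      for (int v = q - 1; v <= w - 1; ++v) {
        w_[v] = std::exp(w_[v] - mx);
        tot += w_[v];
      }
      double r = unif_rand() * tot, acc = 0.0;
      int vsel = w - 1;
      for (int v = q - 1; v <= w - 1; ++v) {
        acc += w_[v];
        if (r <= acc) { vsel = v; break; }
      }
      lv.push_back(mc.postmean(vsel + 1, w)); // segment (vsel, w]
      gp.push_back(vsel);
      w = vsel;
    }
    lv.push_back(mc.postmean(1, w)); // leftmost segment
    std::reverse(gp.begin(), gp.end());
    std::reverse(lv.begin(), lv.end());
    gaps[s] = IntegerVector(gp.begin(), gp.end());
    levels[s] = NumericVector(lv.begin(), lv.end());
  }
  return List::create(_["gaps"] = gaps, _["levels"] = levels);
}
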