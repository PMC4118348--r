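#include <Rcpp.h>
#include <cmath>
#include <functional>
using namespace Rcpp;

// Per-pixel Gaussian-mixture background update.
//
// State matrices are G x P (components in rows, pixels in columns), kept
// sorted per pixel in non-increasing w/sigma order between calls. `x` is the
// new frame flattened to length P. For a circular channel (hue) distances and
// mean updates follow the shortest arc modulo `range`.
//
// Matching is best-match-only: the first component in rank order whose
// distance d satisfies d < c * sigma. The pixel is background (mask 0) when
// that component lies within the background prefix B, the smallest prefix
// whose cumulative weight exceeds T. No match: the lowest-ranked component is
// replaced by one centred at the pixel value. Weights are renormalised to
// sum 1 after every update.
//
// [[Rcpp::export]]
IntegerVector gmm_update_cpp(NumericMatrix mu, NumericMatrix sigma,
                             NumericMatrix w, NumericVector x,
                             double alpha, double cmatch, double Tbg,
                             double sigma0, double w0, double sigma_min,
                             bool circular, double range,
                             double rho_override) {
  const int G = mu.nrow();
  const int P = mu.ncol();
  IntegerVector mask(P);
  const double inv_sqrt2pi = 0.3989422804014327;
  std::vector<int> ord(G);

  for (int p = 0; p < P; ++p) {
    const double xv = x[p];

    // background prefix B (components are sorted by w/sigma)
    int B = G;
    double cum = 0.0;
    for (int i = 0; i < G; ++i) {
      cum += w(i, p);
      if (cum > Tbg) { B = i + 1; break; }
    }

    // best match in rank order
    int m = -1;
    double dm = 0.0, diffm = 0.0;
    for (int i = 0; i < G; ++i) {
      double diff = xv - mu(i, p);
      if (circular) {
        // both values live in [0, range), so diff is in (-range, range)
        if (diff > range / 2.0)  diff -= range;
        if (diff < -range / 2.0) diff += range;
      }
      double d = std::fabs(diff);
      if (d < cmatch * sigma(i, p)) { m = i; dm = d; diffm = diff; break; }
    }

    if (m >= 0) {
      mask[p] = (m < B) ? 0 : 1;
      // rho = alpha * eta(x | mu, sigma), clamped for stability
      double s = sigma(m, p);
      double rho;
      if (rho_override > 0.0) {
        // calibration phase: running-average sufficient statistics
        rho = rho_override;
      } else {
        double eta = inv_sqrt2pi / s * std::exp(-0.5 * dm * dm / (s * s));
        rho = alpha * eta;
        if (rho < alpha * 1e-4) rho = alpha * 1e-4;
        if (rho > 1.0) rho = 1.0;
      }

      double mu_new = mu(m, p) + rho * diffm;
      if (circular) {
        // rho <= 1 keeps the step inside one wrap of the circle
        if (mu_new < 0)      mu_new += range;
        if (mu_new >= range) mu_new -= range;
      }
      double dnew = xv - mu_new;
      if (circular) {
        if (dnew > range / 2.0)  dnew -= range;
        if (dnew < -range / 2.0) dnew += range;
      }
      double var_new = (1.0 - rho) * s * s + rho * dnew * dnew;
      double s_new = std::sqrt(var_new);
      if (s_new < sigma_min) s_new = sigma_min;
      mu(m, p) = mu_new;
      sigma(m, p) = s_new;
      for (int i = 0; i < G; ++i)
        w(i, p) = (1.0 - alpha) * w(i, p) + (i == m ? alpha : 0.0);
    } else {
      mask[p] = 1;
      // replace the least probable component (lowest w/sigma)
      int r = 0;
      double worst = w(0, p) / sigma(0, p);
      for (int i = 1; i < G; ++i) {
        double q = w(i, p) / sigma(i, p);
        if (q < worst) { worst = q; r = i; }
      }
      mu(r, p) = xv;
      sigma(r, p) = sigma0;
      w(r, p) = w0;
    }

    // renormalise weights
    double tot = 0.0;
    for (int i = 0; i < G; ++i) tot += w(i, p);
    if (tot > 0)
      for (int i = 0; i < G; ++i) w(i, p) /= tot;

    // re-sort components by w/sigma (descending); G is tiny, insertion sort
    for (int i = 0; i < G; ++i) ord[i] = i;
    for (int i = 1; i < G; ++i) {
      int key = ord[i];
      double kq = w(key, p) / sigma(key, p);
      int j = i - 1;
      while (j >= 0 && w(ord[j], p) / sigma(ord[j], p) < kq) {
        ord[j + 1] = ord[j];
        --j;
      }
      ord[j + 1] = key;
    }
    bool sorted = true;
    for (int i = 0; i < G; ++i) if (ord[i] != i) { sorted = false; break; }
    if (!sorted) {
      std::vector<double> tm(G), ts(G), tw(G);
      for (int i = 0; i < G; ++i) {
        tm[i] = mu(ord[i], p); ts[i] = sigma(ord[i], p); tw[i] = w(ord[i], p);
      }
      for (int i = 0; i < G; ++i) {
        mu(i, p) = tm[i]; sigma(i, p) = ts[i]; w(i, p) = tw[i];
      }
    }
  }
  return mask;
}

// 8-connected component labeling of a binary matrix (two-pass union-find).
// Labels are renumbered 1..L in order of first appearance in column-major
// scan; background stays 0.
//
// [[Rcpp::export]]
IntegerMatrix label8_cpp(IntegerMatrix mask) {
  const int M = mask.nrow(), N = mask.ncol();
  IntegerMatrix lab(M, N);
  std::vector<int> parent(1, 0);

  std::function<int(int)> find = [&](int a) {
    while (parent[a] != a) { parent[a] = parent[parent[a]]; a = parent[a]; }
    return a;
  };
  auto unite = [&](int a, int b) {
    a = find(a); b = find(b);
    if (a != b) parent[std::max(a, b)] = std::min(a, b);
  };

  int next = 0;
  for (int j = 0; j < N; ++j) {
    for (int i = 0; i < M; ++i) {
      if (mask(i, j) == 0) continue;
      // neighbours already scanned (column-major): same column above, and
      // previous column rows i-1, i, i+1
      int nb[4] = {0, 0, 0, 0};
      int k = 0;
      if (i > 0 && mask(i - 1, j)) nb[k++] = lab(i - 1, j);
      if (j > 0) {
        if (i > 0 && mask(i - 1, j - 1))     nb[k++] = lab(i - 1, j - 1);
        if (mask(i, j - 1))                  nb[k++] = lab(i, j - 1);
        if (i < M - 1 && mask(i + 1, j - 1)) nb[k++] = lab(i + 1, j - 1);
      }
      if (k == 0) {
        ++next;
        parent.push_back(next);
        lab(i, j) = next;
      } else {
        int mn = nb[0];
        for (int q = 1; q < k; ++q) mn = std::min(mn, nb[q]);
        lab(i, j) = mn;
        for (int q = 0; q < k; ++q) unite(mn, nb[q]);
      }
    }
  }

  // second pass: resolve + renumber by first appearance
  std::vector<int> newlab(next + 1, 0);
  int L = 0;
  for (int j = 0; j < N; ++j)
    for (int i = 0; i < M; ++i)
      if (lab(i, j)) {
        int r = find(lab(i, j));
        if (newlab[r] == 0) newlab[r] = ++L;
        lab(i, j) = newlab[r];
      }
  return lab;
}
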