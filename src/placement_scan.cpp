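// Placement scan for the likelihood engine.
//
// Phase 1 (every edge): the query is attached at the branch midpoint and
// its pendant branch length optimized by golden-section search; the
// per-edge log-likelihood is
//   sum_s log( sum_c sum_x W[x,c,s,e] * P_c(p)[x, q_s] ) + K_e
// where W is the pre-weighted packed edge context (stationary
// frequencies, down/up conditionals and per-site category weights folded
// in by edge_contexts()), P_c(p) = exp(Q * m * r_c * p) from the model's
// symmetric eigendecomposition, q_s the query state, and K_e the sum of
// the per-site log scalers. Sites where the query is missing are
// skipped: they contribute the same constant on every edge and cancel in
// the weight ratios.
//
// Phase 2 (top_k edges): the attachment point along the branch (distal)
// is optimized jointly with the pendant, rebuilding the edge context
// from the packed down/up conditionals at each candidate distal.

#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <algorithm>
using namespace Rcpp;

namespace {

struct Model {
  double L[16], R[16], lam[4], freqs[4];
  std::vector<double> cat_rates;
  double rate;
};

// P(t), row-major
inline void pmat(const Model& m, double t, double* P) {
  double el[4];
  for (int i = 0; i < 4; ++i) el[i] = std::exp(m.lam[i] * t);
  for (int i = 0; i < 4; ++i) {
    for (int j = 0; j < 4; ++j) {
      double acc = 0.0;
      for (int k = 0; k < 4; ++k) acc += m.L[4 * i + k] * el[k] * m.R[4 * k + j];
      P[4 * i + j] = acc > 0.0 ? acc : 0.0;
    }
  }
}

// log-likelihood of one packed buffer: per retained site, 4K contiguous
// weighted context values dotted with the packed transition column of
// the query's state; logs taken in batches to keep the loop
// multiply-only
struct PackedObjective {
  const double* W;            // base of the (nK, S) block for this edge
  const int* sites;           // retained site indices
  const int* qs;              // query state per retained site, 0..3
  int nS, K;
  const Model* m;
  double constant;

  double operator()(double p) const {
    const int nK = 4 * K;
    double P[256];
    for (int c = 0; c < K; ++c) pmat(*m, p * m->rate * m->cat_rates[c], &P[16 * c]);
    double Pq[4][64];
    for (int y = 0; y < 4; ++y)
      for (int c = 0; c < K; ++c)
        for (int x = 0; x < 4; ++x)
          Pq[y][c * 4 + x] = P[16 * c + 4 * x + y];
    double total = 0.0, prod = 1.0;
    int batch = 0;
    if (K == 4) {
      // fully unrolled fast path for the default 4-category model
      for (int si = 0; si < nS; ++si) {
        const double* __restrict w = W + (size_t)sites[si] * 16;
        const double* __restrict pq = Pq[qs[si]];
        double v0 = w[0] * pq[0] + w[4] * pq[4] + w[8] * pq[8] + w[12] * pq[12];
        double v1 = w[1] * pq[1] + w[5] * pq[5] + w[9] * pq[9] + w[13] * pq[13];
        double v2 = w[2] * pq[2] + w[6] * pq[6] + w[10] * pq[10] + w[14] * pq[14];
        double v3 = w[3] * pq[3] + w[7] * pq[7] + w[11] * pq[11] + w[15] * pq[15];
        prod *= (v0 + v1) + (v2 + v3);
        if (++batch == 48) {
          total += std::log(prod);
          prod = 1.0; batch = 0;
        }
      }
    } else {
      for (int si = 0; si < nS; ++si) {
        const double* w = W + (size_t)sites[si] * nK;
        const double* pq = Pq[qs[si]];
        double v0 = 0.0, v1 = 0.0, v2 = 0.0, v3 = 0.0;
        for (int j = 0; j < nK; j += 4) {
          v0 += w[j] * pq[j];
          v1 += w[j + 1] * pq[j + 1];
          v2 += w[j + 2] * pq[j + 2];
          v3 += w[j + 3] * pq[j + 3];
        }
        prod *= (v0 + v1) + (v2 + v3);
        if (++batch == 48) {
          total += std::log(prod);
          prod = 1.0; batch = 0;
        }
      }
    }
    total += std::log(prod);
    return total + constant;
  }
};

// golden-section maximization on [a, b]; also probes the lower boundary
template <typename F>
double golden_max(const F& f, double a, double b, double tol, double* fbest) {
  const double gr = 0.6180339887498949;
  double x1 = b - gr * (b - a), x2 = a + gr * (b - a);
  double f1 = f(x1), f2 = f(x2);
  while (b - a > tol) {
    if (f1 >= f2) {
      b = x2; x2 = x1; f2 = f1;
      x1 = b - gr * (b - a); f1 = f(x1);
    } else {
      a = x1; x1 = x2; f1 = f2;
      x2 = a + gr * (b - a); f2 = f(x2);
    }
  }
  double xm = (a + b) / 2.0, fm = f(xm);
  double f0 = f(0.0);
  if (f0 >= fm) { xm = 0.0; fm = f0; }
  *fbest = fm;
  return xm;
}

} // namespace

// [[Rcpp::export(name = ".scan_place_cpp")]]
NumericMatrix scan_place_cpp(NumericVector pack, NumericMatrix mx,
                             NumericVector Dpack, NumericVector Upack,
                             NumericVector brlen, IntegerVector qstate,
                             NumericMatrix eig_left, NumericMatrix eig_right,
                             NumericVector eig_values, NumericVector freqs,
                             NumericVector cat_rates, double rate,
                             double pendant_max, double tol, int top_k) {
  IntegerVector dims = pack.attr("dim");
  const int nK = dims[0], S = dims[1], E = dims[2];
  const int K = nK / 4;
  if (qstate.size() != S) stop("query state vector does not match context sites");
  const bool refine = top_k > 0 && Dpack.size() > 0;

  Model m;
  m.rate = rate;
  m.cat_rates.assign(cat_rates.begin(), cat_rates.end());
  for (int i = 0; i < 4; ++i) {
    m.lam[i] = eig_values[i];
    m.freqs[i] = freqs[i];
    for (int j = 0; j < 4; ++j) {
      m.L[4 * i + j] = eig_left(i, j);
      m.R[4 * i + j] = eig_right(i, j);
    }
  }
  if (K > 16) stop("at most 16 rate categories supported");

  std::vector<int> sites, qs;
  sites.reserve(S); qs.reserve(S);
  for (int s = 0; s < S; ++s) {
    if (qstate[s] >= 0) { sites.push_back(s); qs.push_back(qstate[s]); }
  }
  const int nS = (int)sites.size();

  const double* P = pack.begin();
  NumericMatrix out(E, 3);

  for (int e = 0; e < E; ++e) {
    double Ke = 0.0;
    for (int si = 0; si < nS; ++si) Ke += mx(sites[si], e);
    PackedObjective obj{P + (size_t)e * nK * S, sites.data(), qs.data(),
                        nS, K, &m, Ke};
    double fbest;
    double pbest = golden_max(obj, 0.0, pendant_max, tol, &fbest);
    out(e, 0) = fbest;
    out(e, 1) = pbest;
    out(e, 2) = brlen[e] / 2.0;
  }

  if (!refine) return out;

  std::vector<int> ord(E);
  for (int e = 0; e < E; ++e) ord[e] = e;
  int k = std::min(top_k, E);
  std::partial_sort(ord.begin(), ord.begin() + k, ord.end(),
                    [&](int a, int b) { return out(a, 0) > out(b, 0); });

  const double* Dp = Dpack.begin();
  const double* Up = Upack.begin();
  std::vector<double> Pa(16 * K), Pb(16 * K);
  std::vector<double> B((size_t)nS * nK);
  std::vector<int> packed_sites(nS);
  for (int si = 0; si < nS; ++si) packed_sites[si] = si;

  for (int r = 0; r < k; ++r) {
    int e = ord[r];
    double b_e = brlen[e];
    const double* De = Dp + (size_t)e * nK * S;
    const double* Ue = Up + (size_t)e * nK * S;
    double Ke = 0.0;
    for (int si = 0; si < nS; ++si) Ke += mx(sites[si], e);

    double best_ll = out(e, 0), best_p = out(e, 1), best_a = out(e, 2);
    // coarse pendant tolerance while searching over the attachment
    // point; the chosen distal gets a final full-precision pendant pass
    double coarse = std::min(pendant_max / 8.0, std::max(tol, 1e-3));
    auto eval_distal = [&](double a_dist, double* p_out, double ptol) {
      for (int c = 0; c < K; ++c) {
        pmat(m, a_dist * rate * m.cat_rates[c], &Pa[16 * c]);
        pmat(m, (b_e - a_dist) * rate * m.cat_rates[c], &Pb[16 * c]);
      }
      for (int si = 0; si < nS; ++si) {
        const double* d = De + (size_t)sites[si] * nK;
        const double* u = Ue + (size_t)sites[si] * nK;
        double* bb = &B[(size_t)si * nK];
        for (int c = 0; c < K; ++c) {
          const double* pa = &Pa[16 * c];
          const double* pb = &Pb[16 * c];
          const double* dc = d + 4 * c;
          const double* uc = u + 4 * c;
          for (int x = 0; x < 4; ++x) {
            double av = pa[4 * x] * dc[0] + pa[4 * x + 1] * dc[1] +
                        pa[4 * x + 2] * dc[2] + pa[4 * x + 3] * dc[3];
            double bv = pb[4 * x] * uc[0] + pb[4 * x + 1] * uc[1] +
                        pb[4 * x + 2] * uc[2] + pb[4 * x + 3] * uc[3];
            bb[4 * c + x] = m.freqs[x] * av * bv;
          }
        }
      }
      PackedObjective obj{B.data(), packed_sites.data(), qs.data(),
                          nS, K, &m, Ke};
      double fb;
      double pb2 = golden_max(obj, 0.0, pendant_max, ptol, &fb);
      *p_out = pb2;
      return fb;
    };

    const double gr = 0.6180339887498949;
    double lo = 0.0, hi = b_e;
    double atol = std::max(tol, 1e-3 * b_e);
    double x1 = hi - gr * (hi - lo), x2 = lo + gr * (hi - lo);
    double p1, p2;
    double f1 = eval_distal(x1, &p1, coarse), f2 = eval_distal(x2, &p2, coarse);
    while (hi - lo > atol) {
      if (f1 >= f2) {
        hi = x2; x2 = x1; f2 = f1;
        x1 = hi - gr * (hi - lo); f1 = eval_distal(x1, &p1, coarse);
      } else {
        lo = x1; x1 = x2; f1 = f2;
        x2 = lo + gr * (hi - lo); f2 = eval_distal(x2, &p2, coarse);
      }
    }
    double am = (lo + hi) / 2.0, pm;
    double fm = eval_distal(am, &pm, tol);
    if (fm >= best_ll) { best_ll = fm; best_p = pm; best_a = am; }
    out(e, 0) = best_ll;
    out(e, 1) = best_p;
    out(e, 2) = best_a;
  }
  return out;
}
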