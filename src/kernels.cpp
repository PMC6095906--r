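#include <Rcpp.h>
#include <R_ext/BLAS.h>
#include <R_ext/Lapack.h>
#include <fftw3.h>
#include <algorithm>
#include <map>
#include <cmath>
using namespace Rcpp;

// Euler-Maruyama integration of coupled stochastic phase oscillators:
//   dphi_i = omega_i dt + sum_j K_ij sin(phi_j - phi_i - lag_ij) dt + noise_it
// Coupling is supplied as an edge list (i, j, K, lag) with i < j; the lag is
// applied antisymmetrically so both endpoints share the same locking point
// phi_j - phi_i = lag. The per-step noise increments (already scaled by
// sigma * sqrt(dt)) come pre-generated from R's RNG for reproducibility.
// [[Rcpp::export]]
List kuramoto_phases(NumericVector phi0, NumericVector omega,
                     IntegerVector ei, IntegerVector ej,
                     NumericVector strength, NumericVector lag,
                     NumericMatrix noise, double dt, NumericMatrix envelope) {
  const int n = phi0.size();
  const int steps = noise.ncol();
  const int m = ei.size();
  NumericMatrix phases(n, steps), data(n, steps);
  std::vector<double> phi(phi0.begin(), phi0.end());
  std::vector<double> drift(n);
  for (int t = 0; t < steps; ++t) {
    std::fill(drift.begin(), drift.end(), 0.0);
    for (int e = 0; e < m; ++e) {
      const int a = ei[e], b = ej[e];
      const double s = std::sin(phi[b] - phi[a] - lag[e]) * strength[e];
      drift[a] += s;
      drift[b] -= s;
    }
    for (int i = 0; i < n; ++i) {
      phi[i] += omega[i] * dt + drift[i] * dt + noise(i, t);
      phases(i, t) = phi[i];
      data(i, t) = envelope(i, t) * std::cos(phi[i]);
    }
  }
  return List::create(_["phases"] = phases, _["data"] = data);
}

// Pairwise phase-locking value and phase lag index from per-channel
// cos(phase) and sin(phase) matrices (samples x channels, so each channel is
// a contiguous column), in one pass.
//   PLV_ij = | mean_t exp(i (phi_i - phi_j)) |
//   PLI_ij = | mean_t sign( sin(phi_i - phi_j) ) |, sign(0) counting as 0
// [[Rcpp::export]]
List phase_metrics_tc(NumericMatrix cosph, NumericMatrix sinph) {
  const int T = cosph.nrow();
  const int n = cosph.ncol();
  NumericMatrix plv(n, n), pli(n, n);
  for (int i = 0; i < n; ++i) {
    const double *ci = &cosph(0, i);
    const double *si = &sinph(0, i);
    for (int j = i + 1; j < n; ++j) {
      const double *cj = &cosph(0, j);
      const double *sj = &sinph(0, j);
      double re = 0.0, im = 0.0, sg = 0.0;
      for (int t = 0; t < T; ++t) {
        const double a = ci[t], b = si[t];
        const double c = cj[t], d = sj[t];
        // exp(i(phi_i - phi_j)) = (a + ib)(c - id)
        re += a * c + b * d;
        const double cross = b * c - a * d; // sin(phi_i - phi_j)
        im += cross;
        sg += (cross > 0.0) - (cross < 0.0);
      }
      const double v = std::sqrt(re * re + im * im) / T;
      const double p = std::fabs(sg) / T;
      plv(i, j) = plv(j, i) = v;
      pli(i, j) = pli(j, i) = p;
    }
  }
  return List::create(_["plv"] = plv, _["pli"] = pli);
}

// ---------------------------------------------------------------------------
// FFTW-backed per-epoch connectivity core.
//
// The analytic (Hilbert) signal of each channel is computed with a cached
// real-to-complex FFT plan plus a complex inverse with the negative
// frequencies zeroed; envelope and normalized phase factors are filled
// directly, avoiding any intermediate complex matrices on the R side.

namespace {

struct AnalyticPlans {
  int T = 0;
  double *rbuf = nullptr;
  fftw_complex *cbuf = nullptr, *zin = nullptr, *zout = nullptr;
  fftw_plan fwd = nullptr, inv = nullptr;
};

AnalyticPlans &analytic_plans(int T) {
  static std::map<int, AnalyticPlans> cache;
  AnalyticPlans &p = cache[T];
  if (p.T != T) {
    p.T = T;
    p.rbuf = fftw_alloc_real(T);
    p.cbuf = fftw_alloc_complex(T / 2 + 1);
    p.zin = fftw_alloc_complex(T);
    p.zout = fftw_alloc_complex(T);
    p.fwd = fftw_plan_dft_r2c_1d(T, p.rbuf, p.cbuf, FFTW_MEASURE);
    p.inv = fftw_plan_dft_1d(T, p.zin, p.zout, FFTW_BACKWARD, FFTW_MEASURE);
  }
  return p;
}

// analytic signal of one channel (strided input), scaled by 1/T
void analytic_channel(const double *x, int stride, int T, AnalyticPlans &p) {
  for (int t = 0; t < T; ++t) p.rbuf[t] = x[(size_t)t * stride];
  fftw_execute(p.fwd);
  std::fill(&p.zin[0][0], &p.zin[0][0] + 2 * T, 0.0);
  p.zin[0][0] = p.cbuf[0][0];
  p.zin[0][1] = p.cbuf[0][1];
  const int half = T / 2;
  const int top = (T % 2 == 0) ? half - 1 : half;
  for (int k = 1; k <= top; ++k) {
    p.zin[k][0] = 2.0 * p.cbuf[k][0];
    p.zin[k][1] = 2.0 * p.cbuf[k][1];
  }
  if (T % 2 == 0) {
    p.zin[half][0] = p.cbuf[half][0];
    p.zin[half][1] = p.cbuf[half][1];
  }
  fftw_execute(p.inv);
}

} // namespace

// Per-epoch connectivity core: input channels x samples, `trim` samples
// dropped from each end of the analytic signal before metric computation.
//   PLV_ij = | mean_t exp(i (phi_i - phi_j)) |
//   PLI_ij = | mean_t sign( sin(phi_i - phi_j) ) |, sign(0) counting as 0
//   AEC_ij = | Pearson correlation of the amplitude envelopes |
// All-zero channels are flagged (their pairs are undefined).
// [[Rcpp::export]]
List conn_all(NumericMatrix x, int trim, bool want_phase, bool want_aec) {
  const int n = x.nrow();
  const int Tfull = x.ncol();
  const int T = Tfull - 2 * trim;
  if (T < 2) stop("edge trim leaves fewer than 2 samples");
  AnalyticPlans &p = analytic_plans(Tfull);
  std::vector<double> env((size_t)T * n), cs, sn;
  if (want_phase) {
    cs.resize((size_t)T * n);
    sn.resize((size_t)T * n);
  }
  LogicalVector flagged(n);
  const double scale = 1.0 / Tfull;
  for (int i = 0; i < n; ++i) {
    analytic_channel(&x(i, 0), n, Tfull, p);
    double tot = 0.0;
    for (int t = 0; t < T; ++t) {
      const double re = p.zout[t + trim][0] * scale;
      const double im = p.zout[t + trim][1] * scale;
      const double e = std::sqrt(re * re + im * im);
      const size_t k = (size_t)i * T + t;
      env[k] = e;
      tot += e;
      if (want_phase) {
        const double d = e > 0 ? e : 1.0;
        cs[k] = re / d;
        sn[k] = im / d;
      }
    }
    flagged[i] = (tot == 0.0);
  }
  List out;
  out["flagged"] = flagged;
  if (want_phase) {
    NumericMatrix plv(n, n), pli(n, n);
    for (int i = 0; i < n; ++i) {
      const double *ci = cs.data() + (size_t)i * T;
      const double *si = sn.data() + (size_t)i * T;
      for (int j = i + 1; j < n; ++j) {
        const double *cj = cs.data() + (size_t)j * T;
        const double *sj = sn.data() + (size_t)j * T;
        double re0 = 0.0, re1 = 0.0, im0 = 0.0, im1 = 0.0, sg0 = 0.0, sg1 = 0.0;
        int t = 0;
        for (; t + 1 < T; t += 2) {
          re0 += ci[t] * cj[t] + si[t] * sj[t];
          re1 += ci[t + 1] * cj[t + 1] + si[t + 1] * sj[t + 1];
          const double x0 = si[t] * cj[t] - ci[t] * sj[t];
          const double x1 = si[t + 1] * cj[t + 1] - ci[t + 1] * sj[t + 1];
          im0 += x0;
          im1 += x1;
          sg0 += (x0 > 0.0) - (x0 < 0.0);
          sg1 += (x1 > 0.0) - (x1 < 0.0);
        }
        for (; t < T; ++t) {
          re0 += ci[t] * cj[t] + si[t] * sj[t];
          const double x0 = si[t] * cj[t] - ci[t] * sj[t];
          im0 += x0;
          sg0 += (x0 > 0.0) - (x0 < 0.0);
        }
        const double re = re0 + re1, im = im0 + im1, sg = sg0 + sg1;
        plv(i, j) = plv(j, i) = std::sqrt(re * re + im * im) / T;
        pli(i, j) = pli(j, i) = std::fabs(sg) / T;
      }
    }
    out["plv"] = plv;
    out["pli"] = pli;
  }
  if (want_aec) {
    std::vector<double> gram((size_t)n * n);
    for (int j = 0; j < n; ++j) {
      double *col = env.data() + (size_t)j * T;
      double mean = 0.0;
      for (int t = 0; t < T; ++t) mean += col[t];
      mean /= T;
      for (int t = 0; t < T; ++t) col[t] -= mean;
    }
    const double one = 1.0, zero = 0.0;
    F77_CALL(dsyrk)("U", "T", &n, &T, &one, env.data(), &T, &zero, gram.data(),
                    &n FCONE FCONE);
    NumericMatrix aec(n, n);
    std::vector<double> sdv(n);
    for (int j = 0; j < n; ++j) {
      const double g = gram[(size_t)j * n + j];
      sdv[j] = g > 0 ? std::sqrt(g) : 1.0;
    }
    for (int j = 0; j < n; ++j)
      for (int i = 0; i < j; ++i)
        aec(i, j) = aec(j, i) =
            std::fabs(gram[(size_t)j * n + i] / (sdv[i] * sdv[j]));
    out["aec"] = aec;
  }
  return out;
}

// Zero-phase FIR filtering by FFT convolution with the symmetric kernel
// g = conv(b, rev(b)) (centred, zero-padded edges). Input channels x samples.
// [[Rcpp::export]]
NumericMatrix fir_zero_phase(NumericMatrix x, NumericVector g) {
  const int n = x.nrow();
  const int T = x.ncol();
  const int len = g.size();
  const int half = (len - 1) / 2;
  int nf = T + len;
  for (;; ++nf) { // next 7-smooth length (fast for FFTW), even
    int r = nf;
    for (int f : {2, 3, 5, 7}) while (r % f == 0) r /= f;
    if (r == 1 && nf % 2 == 0) break;
  }
  static std::map<int, AnalyticPlans> cache; // reuse struct: rbuf/cbuf + plans
  AnalyticPlans &p = cache[nf];
  if (p.T != nf) {
    p.T = nf;
    p.rbuf = fftw_alloc_real(nf);
    p.cbuf = fftw_alloc_complex(nf / 2 + 1);
    p.fwd = fftw_plan_dft_r2c_1d(nf, p.rbuf, p.cbuf, FFTW_MEASURE);
    p.inv = fftw_plan_dft_c2r_1d(nf, p.cbuf, p.rbuf, FFTW_MEASURE);
  }
  // spectrum of g (real, since g is symmetric about its centre up to a
  // linear phase we keep explicitly)
  std::vector<double> gre(nf / 2 + 1), gim(nf / 2 + 1);
  std::fill(p.rbuf, p.rbuf + nf, 0.0);
  for (int k = 0; k < len; ++k) p.rbuf[k] = g[k];
  fftw_execute(p.fwd);
  for (int k = 0; k <= nf / 2; ++k) {
    gre[k] = p.cbuf[k][0];
    gim[k] = p.cbuf[k][1];
  }
  NumericMatrix y(n, T);
  const double scale = 1.0 / nf;
  for (int i = 0; i < n; ++i) {
    for (int t = 0; t < T; ++t) p.rbuf[t] = x(i, t);
    std::fill(p.rbuf + T, p.rbuf + nf, 0.0);
    fftw_execute(p.fwd);
    for (int k = 0; k <= nf / 2; ++k) {
      const double a = p.cbuf[k][0], b = p.cbuf[k][1];
      p.cbuf[k][0] = a * gre[k] - b * gim[k];
      p.cbuf[k][1] = a * gim[k] + b * gre[k];
    }
    fftw_execute(p.inv);
    for (int t = 0; t < T; ++t) y(i, t) = p.rbuf[t + half] * scale;
  }
  return y;
}

// Alternating minimization for the closest-orthogonal-matrix weights: given
// the square factor B (X = B Q with Q an orthonormal frame), iterate the
// Procrustes step (SVD of diag(d) B) and the row-rescaling step
// d <- diag(B W U') until the residual stalls. Returns the converged weights
// and the iteration count.
// [[Rcpp::export]]
List com_weights(NumericMatrix B, NumericVector d0, double total, double tol,
                 int maxit) {
  const int n = B.nrow();
  std::vector<double> db(n * n), u(n * n), vt(n * n), s(n),
      bw(n * n), d(d0.begin(), d0.end()), dnew(n);
  std::vector<int> iwork(8 * n);
  // LAPACK workspace query
  int info = 0, lwork = -1;
  double wkopt = 0;
  F77_CALL(dgesdd)("A", &n, &n, db.data(), &n, s.data(), u.data(), &n,
                   vt.data(), &n, &wkopt, &lwork, iwork.data(), &info FCONE);
  lwork = (int)wkopt;
  std::vector<double> work(lwork);
  double err_prev = 0;
  bool have_prev = false;
  int it = 0;
  const double one = 1.0, zero = 0.0;
  while (it < maxit) {
    ++it;
    for (int j = 0; j < n; ++j)
      for (int i = 0; i < n; ++i)
        db[j * n + i] = d[i] * B(i, j);
    F77_CALL(dgesdd)("A", &n, &n, db.data(), &n, s.data(), u.data(), &n,
                     vt.data(), &n, work.data(), &lwork, iwork.data(),
                     &info FCONE);
    if (info != 0) stop("SVD failed in orthogonalization");
    // bw = B %*% W  (W = t(vt)); dnew_i = sum_k bw[i,k] * u[i,k]
    F77_CALL(dgemm)("N", "T", &n, &n, &n, &one, REAL(B), &n, vt.data(), &n,
                    &zero, bw.data(), &n FCONE FCONE);
    double ssq = 0;
    for (int i = 0; i < n; ++i) {
      double acc = 0;
      for (int k = 0; k < n; ++k) acc += bw[k * n + i] * u[k * n + i];
      dnew[i] = acc;
      ssq += acc * acc;
    }
    const double err = total - ssq;
    std::copy(dnew.begin(), dnew.end(), d.begin());
    if (have_prev && std::fabs(err_prev - err) <= tol * std::fabs(total)) break;
    err_prev = err;
    have_prev = true;
  }
  return List::create(_["d"] = NumericVector(d.begin(), d.end()),
                      _["iterations"] = it);
}

namespace {
int uf_find(std::vector<int> &parent, int x) {
  while (parent[x] != x) {
    parent[x] = parent[parent[x]];
    x = parent[x];
  }
  return x;
}
} // namespace

// Kruskal MST on a dense symmetric weight matrix (weights to MINIMISE).
// Deterministic tie-break: edges sorted by (weight, smaller index, larger
// index). Returns (m-1) x 2 one-based edge matrix.
// [[Rcpp::export]]
IntegerMatrix kruskal_mst(NumericMatrix w) {
  const int n = w.nrow();
  struct Edge { double wt; int i, j; };
  std::vector<Edge> edges;
  edges.reserve((size_t)n * (n - 1) / 2);
  for (int i = 0; i < n; ++i)
    for (int j = i + 1; j < n; ++j)
      edges.push_back({w(i, j), i, j});
  std::sort(edges.begin(), edges.end(), [](const Edge &a, const Edge &b) {
    if (a.wt != b.wt) return a.wt < b.wt;
    if (a.i != b.i) return a.i < b.i;
    return a.j < b.j;
  });
  std::vector<int> parent(n);
  for (int i = 0; i < n; ++i) parent[i] = i;
  IntegerMatrix out(n - 1, 2);
  int taken = 0;
  for (const Edge &e : edges) {
    const int ra = uf_find(parent, e.i), rb = uf_find(parent, e.j);
    if (ra == rb) continue;
    parent[ra] = rb;
    out(taken, 0) = e.i + 1;
    out(taken, 1) = e.j + 1;
    if (++taken == n - 1) break;
  }
  return out;
}


// Global topology descriptors of a tree given its (m-1) x 2 one-based edge
// list: degree sequence, diameter in hops (two-sweep BFS), and the maximum
// raw betweenness pair count (computed from component sizes around each
// node, exact on trees).
// [[Rcpp::export]]
List tree_stats(IntegerMatrix edges, int n) {
  const int m = edges.nrow();
  std::vector<int> deg(n, 0), head(n, -1), nxt(2 * m), to(2 * m);
  for (int e = 0; e < m; ++e) {
    const int a = edges(e, 0) - 1, b = edges(e, 1) - 1;
    to[2 * e] = b; nxt[2 * e] = head[a]; head[a] = 2 * e;
    to[2 * e + 1] = a; nxt[2 * e + 1] = head[b]; head[b] = 2 * e + 1;
    ++deg[a]; ++deg[b];
  }
  std::vector<int> order(n), parent(n, -1), depth(n, -1);
  auto bfs = [&](int start) {
    std::fill(depth.begin(), depth.end(), -1);
    int qh = 0, qt = 0;
    order[qt++] = start; depth[start] = 0; parent[start] = -1;
    while (qh < qt) {
      const int v = order[qh++];
      for (int e = head[v]; e != -1; e = nxt[e]) {
        const int w = to[e];
        if (depth[w] < 0) { depth[w] = depth[v] + 1; parent[w] = v; order[qt++] = w; }
      }
    }
    int far = start;
    for (int v = 0; v < n; ++v) if (depth[v] > depth[far]) far = v;
    return far;
  };
  const int far = bfs(0);
  const int far2 = bfs(far);
  const int diameter = depth[far2];
  // subtree sizes from the last BFS tree (rooted at `far`)
  std::vector<double> size(n, 1.0);
  for (int k = n - 1; k >= 1; --k) size[parent[order[k]]] += size[order[k]];
  const double total_pairs = (double)(n - 1) * (n - 2) / 2.0;
  double bc_max = 0.0;
  for (int v = 0; v < n; ++v) {
    double bc = total_pairs;
    double child_sum = 0.0;
    for (int e = head[v]; e != -1; e = nxt[e]) {
      const int w = to[e];
      if (w == parent[v]) continue;
      bc -= size[w] * (size[w] - 1) / 2.0;
      child_sum += size[w];
    }
    if (parent[v] >= 0) {
      const double rest = n - 1 - child_sum;
      bc -= rest * (rest - 1) / 2.0;
    }
    if (bc > bc_max) bc_max = bc;
  }
  return List::create(_["degree"] = IntegerVector(deg.begin(), deg.end()),
                      _["diameter"] = diameter,
                      _["bc_max_raw"] = bc_max);
}
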