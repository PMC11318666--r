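#include <Rcpp.h>
#include <vector>
#include <cstdint>
#include <cmath>

using namespace Rcpp;

// popcount for 64-bit words
static inline int popcnt64(uint64_t x) {
#if defined(__GNUC__) || defined(__clang__)
  return __builtin_popcountll(x);
#else
  int c = 0; while (x) { x &= x - 1; ++c; } return c;
#endif
}

// Co-clustering coefficient matrix.
// adjacency: n x n logical (no self loops, symmetric).
// For each pair (i, j), U = N_i | N_j as bitsets; k = |U|;
// e = number of graph edges with both endpoints in U; coCC = 2e / (k(k-1)).
// [[Rcpp::export]]
NumericMatrix cocc_matrix_cpp(const LogicalMatrix& adjacency) {
  const int n = adjacency.nrow();
  const int words = (n + 63) / 64;
  std::vector<uint64_t> rows((size_t)n * words, 0ull);
  std::vector<int> deg(n, 0);
  for (int i = 0; i < n; ++i) {
    for (int j = 0; j < n; ++j) {
      if (i != j && adjacency(i, j)) {
        rows[(size_t)i * words + j / 64] |= (1ull << (j % 64));
        ++deg[i];
      }
    }
  }
  std::vector<uint64_t> u(words);
  NumericMatrix out(n, n);
  for (int i = 0; i < n; ++i) {
    for (int j = i + 1; j < n; ++j) {
      const uint64_t* ri = &rows[(size_t)i * words];
      const uint64_t* rj = &rows[(size_t)j * words];
      int k = 0;
      for (int w = 0; w < words; ++w) {
        u[w] = ri[w] | rj[w];
        k += popcnt64(u[w]);
      }
      double cocc = 0.0;
      if (k > 1) {
        // count edge endpoints inside U: sum over v in U of |N_v & U|
        long long twice_e = 0;
        for (int w = 0; w < words; ++w) {
          uint64_t bits = u[w];
          while (bits) {
            int b = __builtin_ctzll(bits);
            bits &= bits - 1;
            int v = w * 64 + b;
            const uint64_t* rv = &rows[(size_t)v * words];
            for (int w2 = 0; w2 < words; ++w2)
              twice_e += popcnt64(rv[w2] & u[w2]);
          }
        }
        cocc = (double)twice_e / ((double)k * (k - 1));
      }
      out(i, j) = cocc;
      out(j, i) = cocc;
    }
  }
  return out;
}

// One pass of the error-vector resultant update, plus full iteration loop.
//
// D: target distance matrix with non-finite entries (Inf) marking pairs
//    without constraint; diagonal ignored.
// W: co-clustering weights in [0,1].
// Resultant of bin j: E_j = sum_i W_ij/(N-1)^beta * E_ij; the objective F
// is the sum of resultant norms, both evaluated on the pre-step
// coordinates.  The synchronous coordinate move is the resultant damped
// by 1/(N-1), P_j += E_j/(N-1) (the undamped move is unstable; see the
// package vignette).  All bins move simultaneously.
//
// Returns list(coords, F_values, iterations, converged, final_dF,
// diverged_at).  Uses R's RNG for the coincident-point jitter guard, so
// set.seed() upstream makes runs reproducible.
// [[Rcpp::export]]
List evrc_iterate_cpp(NumericMatrix coords, const NumericMatrix& D,
                      const NumericMatrix& W, double beta, double tol,
                      int max_iter, int patience, int diverge_window) {
  const int n = coords.nrow();
  const double wnorm = std::pow((double)(n - 1), beta);
  const double damp = 1.0 / (double)(n - 1);
  std::vector<double> px(n), py(n), pz(n), ex(n), ey(n), ez(n);
  for (int i = 0; i < n; ++i) {
    px[i] = coords(i, 0); py[i] = coords(i, 1); pz[i] = coords(i, 2);
  }
  // precompute constrained pair list (finite off-diagonal D)
  std::vector<int> pi_, pj_;
  std::vector<double> pd_, pw_;
  pi_.reserve((size_t)n * (n - 1) / 2);
  for (int i = 0; i < n; ++i)
    for (int j = i + 1; j < n; ++j)
      if (R_finite(D(i, j))) {
        pi_.push_back(i); pj_.push_back(j);
        pd_.push_back(D(i, j));
        pw_.push_back(W(i, j) / wnorm);
      }
  const size_t np = pi_.size();
  std::vector<double> Fs;
  Fs.reserve(std::min(max_iter, 100000));
  GetRNGstate();
  double prevF = NA_REAL, dF = NA_REAL;
  bool converged = false;
  int below = 0, rising = 0, diverged_at = -1, it = 0;
  for (it = 0; it < max_iter; ++it) {
    std::fill(ex.begin(), ex.end(), 0.0);
    std::fill(ey.begin(), ey.end(), 0.0);
    std::fill(ez.begin(), ez.end(), 0.0);
    for (size_t p = 0; p < np; ++p) {
      const int i = pi_[p], j = pj_[p];
      double dx = px[i] - px[j], dy = py[i] - py[j], dz = pz[i] - pz[j];
      double d = std::sqrt(dx * dx + dy * dy + dz * dz);
      double gx, gy, gz;             // E_ij = unit(P_i - P_j) * (d - D_ij)
      if (d < 1e-12) {
        // coincident points: unit direction undefined, jitter randomly
        double ux = unif_rand() * 2 - 1, uy = unif_rand() * 2 - 1,
               uz = unif_rand() * 2 - 1;
        double un = std::sqrt(ux * ux + uy * uy + uz * uz);
        if (un < 1e-12) { ux = 1; uy = 0; uz = 0; un = 1; }
        double mag = pd_[p];         // push apart by the full target
        gx = ux / un * mag; gy = uy / un * mag; gz = uz / un * mag;
      } else {
        double c = (d - pd_[p]) / d;
        gx = dx * c; gy = dy * c; gz = dz * c;
      }
      const double w = pw_[p];
      // resultant of bin j gains w*E_ij; bin i gains w*E_ji = -w*E_ij
      ex[j] += w * gx; ey[j] += w * gy; ez[j] += w * gz;
      ex[i] -= w * gx; ey[i] -= w * gy; ez[i] -= w * gz;
    }
    double F = 0.0;
    for (int b = 0; b < n; ++b)
      F += std::sqrt(ex[b] * ex[b] + ey[b] * ey[b] + ez[b] * ez[b]);
    Fs.push_back(F);
    if (!R_finite(F)) { diverged_at = it + 1; break; }
    // synchronous damped move
    for (int b = 0; b < n; ++b) {
      px[b] += damp * ex[b]; py[b] += damp * ey[b]; pz[b] += damp * ez[b];
    }
    if (R_finite(prevF)) {
      dF = std::fabs(F - prevF);
      below = (dF < tol) ? below + 1 : 0;
      if (below >= patience) { converged = true; ++it; break; }
      // true divergence: sustained growth well above the starting level
      rising = (F > prevF) ? rising + 1 : 0;
      if (rising >= diverge_window && F > 10.0 * Fs.front()) {
        diverged_at = it + 1; break;
      }
    }
    prevF = F;
  }
  PutRNGstate();
  int iters = (int)Fs.size();
  NumericMatrix out(n, 3);
  for (int b = 0; b < n; ++b) { out(b, 0) = px[b]; out(b, 1) = py[b]; out(b, 2) = pz[b]; }
  return List::create(_["coords"] = out,
                      _["F_values"] = NumericVector(Fs.begin(), Fs.end()),
                      _["iterations"] = iters,
                      _["converged"] = converged,
                      _["final_dF"] = dF,
                      _["diverged_at"] = diverged_at);
}
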