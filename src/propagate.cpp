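#include <Rcpp.h>
#include <vector>
#include <algorithm>
using namespace Rcpp;

// Exact pmf propagation of a nearest-neighbour walk on Z whose up-probability
// depends on the site only through its residue mod `period`.  probs[k] is the
// mass at site offset + k.  Support grows by one site per step; mass is moved
// by two shifted adds in a fixed order, so results are bit-reproducible.
// [[Rcpp::export]]
List cpp_evolve_line(NumericVector probs, int offset, int steps,
                     NumericVector up, int period) {
  if (steps < 0) stop("steps must be nonnegative");
  if (period < 1 || up.size() != period) stop("up must have length `period`");
  const int len = probs.size();
  const int flen = len + 2 * steps;
  const long long base = (long long)offset - steps;

  // per-index up-probability, fixed for the whole phase
  std::vector<double> ui(flen);
  for (int k = 0; k < flen; ++k) {
    long long r = (base + k) % period;
    if (r < 0) r += period;
    ui[k] = up[(int)r];
  }

  std::vector<double> cur(flen, 0.0), nxt(flen, 0.0);
  for (int k = 0; k < len; ++k) cur[steps + k] = probs[k];

  for (int s = 1; s <= steps; ++s) {
    const int lo = steps - (s - 1), hi = steps + len - 1 + (s - 1);
    std::fill(nxt.begin() + (lo - 1), nxt.begin() + (hi + 2), 0.0);
    for (int k = lo; k <= hi; ++k) {
      const double p = cur[k];
      if (p == 0.0) continue;
      const double u = ui[k];
      nxt[k + 1] += p * u;
      nxt[k - 1] += p * (1.0 - u);
    }
    std::swap(cur, nxt);
  }

  return List::create(_["probs"] = NumericVector(cur.begin(), cur.end()),
                      _["offset"] = (double)base);
}

// Propagate all rows of a wrapped-walk occupation matrix simultaneously.
// M(i, j) = P(wrapped walk is at site j | started at site i); up[j] is the
// up-probability at circle site j (length S = ncol).  If track_drift, the
// expected one-step drift sum_j M(i,j) * (2 up[j] - 1) is accumulated into
// disp[i] before each step, giving the unwrapped expected displacement of
// the phase for every start site.
// [[Rcpp::export]]
List cpp_evolve_wrapped(NumericMatrix M, NumericVector up, int steps,
                        bool track_drift) {
  const int N = M.nrow(), S = M.ncol();
  if (up.size() != S) stop("up must have length ncol(M)");
  std::vector<double> cur(M.begin(), M.end());
  std::vector<double> nxt((size_t)N * S);
  std::vector<double> disp(N, 0.0);

  for (int s = 0; s < steps; ++s) {
    if (track_drift) {
      for (int j = 0; j < S; ++j) {
        const double c = 2.0 * up[j] - 1.0;
        if (c == 0.0) continue;
        const double* col = &cur[(size_t)j * N];
        for (int i = 0; i < N; ++i) disp[i] += col[i] * c;
      }
    }
    std::fill(nxt.begin(), nxt.end(), 0.0);
    for (int j = 0; j < S; ++j) {
      const int ju = (j + 1) % S, jd = (j - 1 + S) % S;
      const double u = up[j], d = 1.0 - u;
      const double* src = &cur[(size_t)j * N];
      double* cu = &nxt[(size_t)ju * N];
      double* cd = &nxt[(size_t)jd * N];
      for (int i = 0; i < N; ++i) {
        cu[i] += src[i] * u;
        cd[i] += src[i] * d;
      }
    }
    std::swap(cur, nxt);
  }

  NumericMatrix out(N, S);
  std::copy(cur.begin(), cur.end(), out.begin());
  return List::create(_["matrix"] = out,
                      _["disp"] = NumericVector(disp.begin(), disp.end()));
}
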