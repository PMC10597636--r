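// Span-constrained partition function and accessibility profiles.
//
// Inside-outside dynamic programming over non-pseudoknotted secondary
// structures in which every base pair (i,j) satisfies
//   min_hairpin + 1 <= j - i <= W.
// Structure energy = sum of pair energies, plus stack_bonus for every
// adjacent stacked pair.  Boltzmann weight exp(-E/RT).
//
// Arithmetic is linear with Vienna-style per-nucleotide rescaling: every
// stored quantity covering m bases is divided by exp(lambda * m), where
// lambda is estimated from a span-constrained max-weight (Nussinov-like)
// pass.  If the partition still over/underflows, the computation retries
// with an adjusted lambda.  Reported values are on the log scale, so the
// scaling cancels exactly.

#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <limits>

using namespace Rcpp;

namespace {

struct FoldParams {
  int N;
  int W;
  int h;        // min hairpin: minimum unpaired bases enclosed by a pair
  double RT;
  double sfac;  // exp(-stack_bonus / RT)
  const std::vector<int>* seq;          // codes 0=A 1=C 2=G 3=U 4=N
  const std::vector<double>* pairlw;    // 25 entries: -E/RT, NaN = forbidden
};

inline double pair_lw(const FoldParams& fp, int i, int j) {
  return (*fp.pairlw)[(*fp.seq)[i] * 5 + (*fp.seq)[j]];
}
inline bool pairable(const FoldParams& fp, int i, int j) {
  int span = j - i;
  if (span < fp.h + 1 || span > fp.W) return false;
  return std::isfinite(pair_lw(fp, i, j));
}

// Max log-weight of any admissible structure (for the scale estimate).
// Stack bonus is over-counted optimistically; only used to size lambda.
double max_logweight(const FoldParams& fp) {
  const int N = fp.N, W = fp.W, h = fp.h;
  const int Lmax = std::min(W - 1, N);
  double stack_extra = std::max(0.0, std::log(fp.sfac));
  // Mn[i][len]: best log-weight on interval [i, i+len-1], len <= Lmax
  std::vector<double> Mn((size_t)(N + 1) * (Lmax + 1), 0.0);
  std::vector<double> Bn((size_t)N * (W + 1),
                         -std::numeric_limits<double>::infinity());
  auto mn = [&](int i, int len) -> double& {
    return Mn[(size_t)i * (Lmax + 1) + len];
  };
  auto bn = [&](int i, int span) -> double& {
    return Bn[(size_t)i * (W + 1) + span];
  };
  for (int B = 1; B <= std::min(N, W + 1); ++B) {
    int span = B - 1;
    if (span >= h + 1 && span <= W) {
      for (int i = 0; i + span < N; ++i) {
        int j = i + span;
        if (!pairable(fp, i, j)) continue;
        double v = pair_lw(fp, i, j) + stack_extra;
        if (span - 2 >= 1) v += mn(i + 1, span - 1);
        bn(i, span) = v;
      }
    }
    if (B <= Lmax) {
      for (int i = 0; i + B <= N; ++i) {
        int j = i + B - 1;
        double best = mn(i, B - 1);
        for (int k = std::max(i, j - W); k <= j - h - 1; ++k) {
          double bv = bn(k, j - k);
          if (!std::isfinite(bv)) continue;
          double v = (k > i ? mn(i, k - i) : 0.0) + bv;
          if (v > best) best = v;
        }
        mn(i, B) = best;
      }
    }
  }
  // prefix pass
  std::vector<double> Mp(N + 1, 0.0);
  for (int t = 1; t <= N; ++t) {
    double best = Mp[t - 1];
    int j = t - 1;
    for (int k = std::max(0, j - W); k <= j - h - 1; ++k) {
      double bv = bn(k, j - k);
      if (!std::isfinite(bv)) continue;
      double v = Mp[k] + bv;
      if (v > best) best = v;
    }
    Mp[t] = best;
  }
  return Mp[N];
}

struct FoldState {
  int Lmax;
  double lambda;
  bool ok;
  std::vector<double> Zb, Zi, Ozb, Ozi, F, G;
};

// One inside(+optional outside) pass at a fixed scale factor.
void fold_pass(const FoldParams& fp, double lambda, bool outside,
               FoldState& st) {
  const int N = fp.N, W = fp.W, h = fp.h;
  const int Lmax = std::max(0, std::min(W - 1, N));
  st.Lmax = Lmax;
  st.lambda = lambda;
  st.ok = true;
  const double u = std::exp(-lambda);
  const size_t nzb = (size_t)N * (W + 1);
  const size_t nzi = (size_t)(N + 1) * (Lmax + 1);
  st.Zb.assign(nzb, 0.0);
  st.Zi.assign(nzi, 1.0);  // len-0 intervals = 1; overwritten for len >= 1
  st.F.assign(N + 1, 1.0);
  st.G.assign(N + 1, 1.0);
  auto zb = [&](int i, int span) -> double& {
    return st.Zb[(size_t)i * (W + 1) + span];
  };
  auto zi = [&](int i, int len) -> double& {
    return st.Zi[(size_t)i * (Lmax + 1) + len];
  };

  for (int B = 1; B <= std::min(N, W + 1); ++B) {
    int span = B - 1;
    if (span >= h + 1 && span <= W) {
      for (int i = 0; i + span < N; ++i) {
        int j = i + span;
        if (!pairable(fp, i, j)) continue;
        double w = std::exp(pair_lw(fp, i, j) - 2.0 * lambda);
        double inner = (span - 1 <= Lmax) ? zi(i + 1, span - 1) : 0.0;
        double v = inner;
        if (span - 2 >= h + 1) v += (fp.sfac - 1.0) * zb(i + 1, span - 2);
        zb(i, span) = w * v;
      }
    }
    if (B <= Lmax) {
      for (int i = 0; i + B <= N; ++i) {
        int j = i + B - 1;
        double acc = u * zi(i, B - 1);
        for (int k = i; k <= j - h - 1; ++k)
          acc += zi(i, k - i) * zb(k, j - k);
        zi(i, B) = acc;
      }
    }
  }
  for (int t = 1; t <= N; ++t) {
    int j = t - 1;
    double acc = u * st.F[t - 1];
    for (int k = std::max(0, j - W); k <= j - h - 1; ++k)
      acc += st.F[k] * zb(k, j - k);
    st.F[t] = acc;
  }
  for (int t = N - 1; t >= 0; --t) {
    double acc = u * st.G[t + 1];
    for (int j = t + h + 1; j <= std::min(N - 1, t + W); ++j)
      acc += zb(t, j - t) * st.G[j + 1];
    st.G[t] = acc;
  }
  if (!std::isfinite(st.F[N]) || st.F[N] <= 0.0) { st.ok = false; return; }

  if (!outside) return;

  st.Ozb.assign(nzb, 0.0);
  st.Ozi.assign(nzi, 0.0);
  auto ozb = [&](int i, int span) -> double& {
    return st.Ozb[(size_t)i * (W + 1) + span];
  };
  auto ozi = [&](int i, int len) -> double& {
    return st.Ozi[(size_t)i * (Lmax + 1) + len];
  };
  // exterior-loop occurrences of each pair
  for (int i = 0; i < N; ++i) {
    for (int span = h + 1; span <= std::min(W, N - 1 - i); ++span) {
      if (zb(i, span) > 0.0) ozb(i, span) = st.F[i] * st.G[i + span + 1];
    }
  }
  // descending interval size; intervals first, then pairs of that size
  for (int B = std::min(N, W + 1); B >= 1; --B) {
    if (B <= Lmax) {
      for (int i = 0; i + B <= N; ++i) {
        double out = ozi(i, B);
        if (out == 0.0) continue;
        int j = i + B - 1;
        ozi(i, B - 1) += u * out;
        for (int k = i; k <= j - h - 1; ++k) {
          double zbkj = zb(k, j - k);
          if (zbkj == 0.0) continue;
          double zik = zi(i, k - i);
          if (k > i) ozi(i, k - i) += out * zbkj;
          ozb(k, j - k) += out * zik;
        }
      }
    }
    int span = B - 1;
    if (span >= h + 1 && span <= W) {
      for (int i = 0; i + span < N; ++i) {
        double out = ozb(i, span);
        if (out == 0.0 || zb(i, span) == 0.0) continue;
        int j = i + span;
        double w = std::exp(pair_lw(fp, i, j) - 2.0 * lambda);
        if (span - 1 <= Lmax) ozi(i + 1, span - 1) += out * w;
        if (span - 2 >= h + 1)
          ozb(i + 1, span - 2) += out * w * (fp.sfac - 1.0);
      }
    }
  }
}

// Zu for window [a, a+la-1] (scaled to the whole sequence).
double window_zu(const FoldParams& fp, const FoldState& st, int a, int la) {
  const int N = fp.N, W = fp.W;
  const int b = a + la - 1;
  const double ul = std::exp(-st.lambda * la);
  auto zb = [&](int i, int span) -> double {
    return st.Zb[(size_t)i * (W + 1) + span];
  };
  auto ozb = [&](int i, int span) -> double {
    return st.Ozb[(size_t)i * (W + 1) + span];
  };
  auto zi = [&](int i, int len) -> double {
    return st.Zi[(size_t)i * (st.Lmax + 1) + len];
  };
  double zu = st.F[a] * st.G[b + 1] * ul;
  // innermost pair (p,q) enclosing the window
  for (int p = std::max(0, b + 1 - W); p <= a - 1; ++p) {
    int qmax = std::min(N - 1, p + W);
    for (int q = b + 1; q <= qmax; ++q) {
      if (!pairable(fp, p, q)) continue;
      double o = ozb(p, q - p);
      if (o == 0.0 || zb(p, q - p) == 0.0) continue;
      double w = std::exp(pair_lw(fp, p, q) - 2.0 * st.lambda);
      zu += o * w * zi(p + 1, a - 1 - p) * zi(b + 1, q - b - 1) * ul;
    }
  }
  return zu;
}

void make_params(const IntegerVector& seq, const NumericVector& pairlw,
                 double stack_bonus, int min_hairpin, double rt, int W,
                 FoldParams& fp, std::vector<int>& codes,
                 std::vector<double>& plw) {
  fp.N = seq.size();
  fp.W = W;
  fp.h = min_hairpin;
  fp.RT = rt;
  fp.sfac = std::exp(-stack_bonus / rt);
  codes.assign(seq.begin(), seq.end());
  plw.assign(pairlw.begin(), pairlw.end());
  fp.seq = &codes;
  fp.pairlw = &plw;
}

bool run_with_rescue(const FoldParams& fp, bool outside, FoldState& st) {
  double base = 0.0;
  if (fp.N > 0) base = std::max(0.0, max_logweight(fp) / fp.N);
  const double bumps[] = {0.5, -0.3, 1.5, -0.45, 3.0, 6.0};
  for (double bump : bumps) {
    fold_pass(fp, base + bump, outside, st);
    if (st.ok) return true;
  }
  return false;
}

}  // namespace

// [[Rcpp::export]]
List cpp_access_profile(IntegerVector seq, NumericVector pairlw,
                        double stack_bonus, int min_hairpin, double rt,
                        int W, int la) {
  FoldParams fp;
  std::vector<int> codes;
  std::vector<double> plw;
  make_params(seq, pairlw, stack_bonus, min_hairpin, rt, W, fp, codes, plw);
  const int N = fp.N;
  if (N < la) stop("sequence shorter than the window length l_a");
  FoldState st;
  if (!run_with_rescue(fp, true, st))
    stop("partition function over/underflowed at every rescale attempt");
  const double logZ = std::log(st.F[N]);
  NumericVector prof(N - la + 1);
  for (int a = 0; a + la <= N; ++a) {
    double zu = window_zu(fp, st, a, la);
    if (!(zu > 0.0) || !std::isfinite(zu))
      stop("unpaired partition underflowed for a window");
    double acc = -rt * (std::log(zu) - logZ);
    prof[a] = acc;
  }
  return List::create(_["profile"] = prof,
                      _["log_z"] = logZ + st.lambda * N);
}

// [[Rcpp::export]]
List cpp_partition(IntegerVector seq, NumericVector pairlw,
                   double stack_bonus, int min_hairpin, double rt, int W) {
  FoldParams fp;
  std::vector<int> codes;
  std::vector<double> plw;
  make_params(seq, pairlw, stack_bonus, min_hairpin, rt, W, fp, codes, plw);
  const int N = fp.N;
  FoldState st;
  if (!run_with_rescue(fp, false, st))
    stop("partition function over/underflowed at every rescale attempt");
  NumericMatrix log_zb(N, N);
  std::fill(log_zb.begin(), log_zb.end(),
            -std::numeric_limits<double>::infinity());
  for (int i = 0; i < N; ++i)
    for (int span = min_hairpin + 1; span <= std::min(W, N - 1 - i); ++span) {
      double v = st.Zb[(size_t)i * (W + 1) + span];
      if (v > 0.0) log_zb(i, i + span) = std::log(v) + st.lambda * (span + 1);
    }
  NumericVector log_prefix(N + 1);
  for (int t = 0; t <= N; ++t)
    log_prefix[t] = std::log(st.F[t]) + st.lambda * t;
  return List::create(_["log_z"] = log_prefix[N],
                      _["log_zb"] = log_zb,
                      _["log_prefix"] = log_prefix,
                      _["scale_lambda"] = st.lambda);
}
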