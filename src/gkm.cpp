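// Gapped k-mer machinery: 2-bit window encoding, the mismatch-count kernel
// identity sum_m cnt[m] * C(l-m, k), explicit (gap-pattern, k-string) feature
// weight vectors, and exhaustive l-mer scoring.  l is capped at 15 so a
// window fits 30 bits of a uint32.
#include <Rcpp.h>
#include <cstdint>
#include <vector>
#include <string>
#include <cmath>
using namespace Rcpp;

static inline int base_code(char c) {
  switch (c) {
    case 'A': case 'a': return 0;
    case 'C': case 'c': return 1;
    case 'G': case 'g': return 2;
    case 'T': case 't': return 3;
  }
  return -1;
}

static const char BASES[4] = {'A', 'C', 'G', 'T'};

static inline uint32_t rc_code(uint32_t x, int l) {
  uint32_t r = 0;
  for (int i = 0; i < l; ++i) {
    r = (r << 2) | (3u - (x & 3u));
    x >>= 2;
  }
  return r;
}

// number of mismatching base positions between two encoded windows
static inline int mm_count(uint32_t a, uint32_t b) {
  uint32_t x = a ^ b;
  x = (x | (x >> 1)) & 0x55555555u;
  return __builtin_popcount(x);
}

// forward l-windows of a sequence; windows containing non-ACGT are skipped
static std::vector<uint32_t> encode_fwd(const std::string& s, int l) {
  std::vector<uint32_t> v;
  int n = (int)s.size();
  if (n < l) return v;
  v.reserve(n - l + 1);
  uint32_t code = 0;
  uint32_t mask = (1u << (2 * l)) - 1u;
  int run = 0;
  for (int i = 0; i < n; ++i) {
    int b = base_code(s[i]);
    if (b < 0) { run = 0; code = 0; continue; }
    code = ((code << 2) | (uint32_t)b) & mask;
    if (++run >= l) v.push_back(code);
  }
  return v;
}

// forward plus reverse-complement windows (the both-strand feature map)
static std::vector<uint32_t> encode_full(const std::string& s, int l) {
  std::vector<uint32_t> fwd = encode_fwd(s, l);
  std::vector<uint32_t> v = fwd;
  v.reserve(2 * fwd.size());
  for (size_t i = 0; i < fwd.size(); ++i) v.push_back(rc_code(fwd[i], l));
  return v;
}

// wt[m] = C(l - m, k), zero once l - m < k
static std::vector<double> mismatch_weights(int l, int k) {
  std::vector<double> wt(l + 1, 0.0);
  for (int m = 0; m <= l - k; ++m)
    wt[m] = Rf_choose((double)(l - m), (double)k);
  return wt;
}

// raw inner product of both-strand gapped k-mer count vectors.
// With WA = fwd(a) u rc(a) etc., <phi(a), phi(b)> =
//   2 * sum_{wa in fwd(a)} sum_{wb in WA(b)} C(l - mm(wa, wb), k).
static double raw_dot(const std::vector<uint32_t>& fwdA,
                      const std::vector<uint32_t>& fullB,
                      const std::vector<double>& wt, int maxm) {
  double acc = 0.0;
  for (size_t i = 0; i < fwdA.size(); ++i) {
    uint32_t wa = fwdA[i];
    for (size_t j = 0; j < fullB.size(); ++j) {
      int m = mm_count(wa, fullB[j]);
      if (m <= maxm) acc += wt[m];
    }
  }
  return 2.0 * acc;
}

static void check_lk(int l, int k) {
  if (l < 1 || l > 15) stop("l must be in 1..15");
  if (k < 1 || k > l) stop("k must satisfy 1 <= k <= l");
}

// [[Rcpp::export]]
NumericVector cpp_self_raw(CharacterVector seqs, int l, int k) {
  check_lk(l, k);
  std::vector<double> wt = mismatch_weights(l, k);
  int maxm = l - k;
  int n = seqs.size();
  NumericVector out(n);
  for (int i = 0; i < n; ++i) {
    std::string s = as<std::string>(seqs[i]);
    std::vector<uint32_t> f = encode_fwd(s, l), u = encode_full(s, l);
    out[i] = f.empty() ? 0.0 : raw_dot(f, u, wt, maxm);
  }
  return out;
}

// [[Rcpp::export]]
NumericMatrix cpp_gkm_raw_cross(CharacterVector A, CharacterVector B,
                                int l, int k) {
  check_lk(l, k);
  std::vector<double> wt = mismatch_weights(l, k);
  int maxm = l - k;
  int na = A.size(), nb = B.size();
  std::vector<std::vector<uint32_t> > fa(na), ub(nb);
  for (int i = 0; i < na; ++i) fa[i] = encode_fwd(as<std::string>(A[i]), l);
  for (int j = 0; j < nb; ++j) ub[j] = encode_full(as<std::string>(B[j]), l);
  NumericMatrix K(na, nb);
  for (int i = 0; i < na; ++i) {
    if (i % 16 == 0) Rcpp::checkUserInterrupt();
    for (int j = 0; j < nb; ++j)
      K(i, j) = fa[i].empty() ? 0.0 : raw_dot(fa[i], ub[j], wt, maxm);
  }
  return K;
}

// [[Rcpp::export]]
NumericMatrix cpp_gkm_raw_sym(CharacterVector A, int l, int k) {
  check_lk(l, k);
  std::vector<double> wt = mismatch_weights(l, k);
  int maxm = l - k;
  int n = A.size();
  std::vector<std::vector<uint32_t> > fa(n), ua(n);
  for (int i = 0; i < n; ++i) {
    std::string s = as<std::string>(A[i]);
    fa[i] = encode_fwd(s, l);
    ua[i] = encode_full(s, l);
  }
  NumericMatrix K(n, n);
  for (int i = 0; i < n; ++i) {
    if (i % 8 == 0) Rcpp::checkUserInterrupt();
    for (int j = i; j < n; ++j) {
      double v = fa[i].empty() ? 0.0 : raw_dot(fa[i], ua[j], wt, maxm);
      K(i, j) = v;
      K(j, i) = v;
    }
  }
  return K;
}

// gap patterns: all C(l,k) choices of k informative positions, as per-pattern
// bit shifts into the window code (position 0 = leftmost base = high bits)
static std::vector<std::vector<int> > gap_patterns(int l, int k) {
  std::vector<std::vector<int> > out;
  std::vector<int> idx(k);
  for (int i = 0; i < k; ++i) idx[i] = i;
  while (true) {
    std::vector<int> shifts(k);
    for (int i = 0; i < k; ++i) shifts[i] = 2 * (l - 1 - idx[i]);
    out.push_back(shifts);
    int i = k - 1;
    while (i >= 0 && idx[i] == l - k + i) --i;
    if (i < 0) break;
    ++idx[i];
    for (int j = i + 1; j < k; ++j) idx[j] = idx[j - 1] + 1;
  }
  return out;
}

static inline uint32_t gather_k(uint32_t w, const std::vector<int>& shifts) {
  uint32_t code = 0;
  for (size_t j = 0; j < shifts.size(); ++j)
    code = (code << 2) | ((w >> shifts[j]) & 3u);
  return code;
}

// accumulate w_vec = sum_i coef_i * phi(sv_i) over (pattern, k-string)
// features; coef_i should already carry the per-SV kernel normalization
// [[Rcpp::export]]
NumericVector cpp_feature_weights(CharacterVector svs, NumericVector coefs,
                                  int l, int k) {
  check_lk(l, k);
  if (2 * k > 28) stop("k too large for dense feature vector");
  std::vector<std::vector<int> > pats = gap_patterns(l, k);
  size_t P = pats.size();
  size_t dim = P << (2 * k);
  NumericVector wv((R_xlen_t)dim);
  for (int i = 0; i < svs.size(); ++i) {
    Rcpp::checkUserInterrupt();
    std::vector<uint32_t> wins = encode_full(as<std::string>(svs[i]), l);
    double c = coefs[i];
    for (size_t t = 0; t < wins.size(); ++t) {
      uint32_t w = wins[t];
      for (size_t p = 0; p < P; ++p) {
        size_t off = (p << (2 * k)) | gather_k(w, pats[p]);
        wv[(R_xlen_t)off] += c;
      }
    }
  }
  return wv;
}

// normalized decision contribution <w_vec, phi(x)> / ||phi(x)|| for every
// l-mer x (feature map of a bare l-mer has windows {x, rc(x)});
// out[x] == out[rc(x)] by construction.  Instead of gathering 2 * C(l,k)
// features per l-mer, each (pattern, k-string) weight is scattered once
// onto the 4^(l-k) l-mers that contain it: acc[x] = sum_p wv[p, x|_p],
// then raw(x) = acc[x] + acc[rc(x)].
// [[Rcpp::export]]
NumericVector cpp_score_all_kmers(NumericVector wv, int l, int k) {
  check_lk(l, k);
  if (l > 13) stop("l > 13 exceeds the exhaustive-scoring guard");
  std::vector<std::vector<int> > pats = gap_patterns(l, k);
  size_t P = pats.size();
  std::vector<double> wt = mismatch_weights(l, k);
  double wt0 = wt[0];
  size_t N = (size_t)1 << (2 * l);
  int g = l - k;
  size_t nk = (size_t)1 << (2 * k), ng = (size_t)1 << (2 * g);
  std::vector<double> acc(N, 0.0);
  std::vector<uint32_t> offs(ng);
  for (size_t p = 0; p < P; ++p) {
    Rcpp::checkUserInterrupt();
    // gap-position shifts = complement of the pattern's informative shifts
    std::vector<char> is_info(l, 0);
    for (size_t j = 0; j < pats[p].size(); ++j)
      is_info[l - 1 - pats[p][j] / 2] = 1;
    std::vector<int> gap_shifts;
    for (int i = 0; i < l; ++i)
      if (!is_info[i]) gap_shifts.push_back(2 * (l - 1 - i));
    for (size_t c = 0; c < ng; ++c) {
      uint32_t off = 0, cc = (uint32_t)c;
      for (int j = g - 1; j >= 0; --j) {
        off |= (cc & 3u) << gap_shifts[j];
        cc >>= 2;
      }
      offs[c] = off;
    }
    const double* wvp = &wv[0] + (p << (2 * k));
    for (size_t ks = 0; ks < nk; ++ks) {
      double v = wvp[ks];
      if (v == 0.0) continue;
      uint32_t base = 0, kk = (uint32_t)ks;
      for (int j = k - 1; j >= 0; --j) {
        base |= (kk & 3u) << pats[p][j];
        kk >>= 2;
      }
      for (size_t c = 0; c < ng; ++c) acc[base | offs[c]] += v;
    }
  }
  NumericVector out((R_xlen_t)N);
  for (size_t x = 0; x < N; ++x) {
    uint32_t r = rc_code((uint32_t)x, l);
    if ((size_t)r < x) continue;
    if ((x & 0xFFFFF) == 0) Rcpp::checkUserInterrupt();
    double raw = acc[x] + acc[r];
    int m = mm_count((uint32_t)x, r);
    double val = raw / std::sqrt(2.0 * (wt0 + wt[m]));
    out[(R_xlen_t)x] = val;
    out[(R_xlen_t)r] = val;
  }
  return out;
}

static std::string decode_kmer(uint32_t x, int l) {
  std::string s(l, 'A');
  for (int i = l - 1; i >= 0; --i) {
    s[i] = BASES[x & 3u];
    x >>= 2;
  }
  return s;
}

// [[Rcpp::export]]
CharacterVector cpp_enumerate_canonical(int l) {
  if (l < 1) stop("l must be >= 1");
  if (l > 13) stop("l > 13 exceeds the enumeration guard");
  size_t N = (size_t)1 << (2 * l);
  std::vector<std::string> v;
  v.reserve(N / 2 + (1u << l));
  for (size_t x = 0; x < N; ++x) {
    if ((x & 0xFFFFF) == 0) Rcpp::checkUserInterrupt();
    uint32_t r = rc_code((uint32_t)x, l);
    if ((size_t)r >= x) v.push_back(decode_kmer((uint32_t)x, l));
  }
  return wrap(v);
}

// [[Rcpp::export]]
IntegerVector cpp_encode_kmers(CharacterVector kmers, int l) {
  check_lk(l, l);
  int n = kmers.size();
  IntegerVector out(n);
  for (int i = 0; i < n; ++i) {
    std::string s = as<std::string>(kmers[i]);
    if ((int)s.size() != l) stop("k-mer length mismatch");
    uint32_t code = 0;
    for (int j = 0; j < l; ++j) {
      int b = base_code(s[j]);
      if (b < 0) stop("non-ACGT character in k-mer");
      code = (code << 2) | (uint32_t)b;
    }
    out[i] = (int)code;
  }
  return out;
}

// sliding sum of per-window table weights over one sequence; table is the
// full 4^l vector (strand-symmetric values); returns sum, best 0-based
// window offset and window count
// [[Rcpp::export]]
List cpp_sliding_scan(std::string seq, NumericVector table, int l) {
  int n = (int)seq.size();
  double acc = 0.0, best = R_NegInf;
  int best_off = -1, nwin = 0;
  if (n >= l) {
    uint32_t code = 0;
    uint32_t mask = (1u << (2 * l)) - 1u;
    int run = 0;
    for (int i = 0; i < n; ++i) {
      int b = base_code(seq[i]);
      if (b < 0) { run = 0; code = 0; continue; }
      code = ((code << 2) | (uint32_t)b) & mask;
      if (++run >= l) {
        double w = table[(R_xlen_t)code];
        acc += w;
        ++nwin;
        int off = i - l + 1;
        if (w > best) { best = w; best_off = off; }
      }
    }
  }
  return List::create(_["sum"] = acc, _["best_offset"] = best_off,
                      _["best_weight"] = (nwin ? best : NA_REAL),
                      _["n_windows"] = nwin);
}
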