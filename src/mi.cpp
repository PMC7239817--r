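#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <cstdint>
using namespace Rcpp;

// splitmix64: small deterministic generator so every pair gets its own
// reproducible permutation stream independent of evaluation order
static inline uint64_t splitmix64(uint64_t &state) {
  uint64_t z = (state += 0x9E3779B97F4A7C15ULL);
  z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
  z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
  return z ^ (z >> 31);
}

static inline int rand_below(uint64_t &state, int n) {
  // rejection sampling to avoid modulo bias
  uint64_t limit = UINT64_MAX - (UINT64_MAX % (uint64_t)n);
  uint64_t x;
  do { x = splitmix64(state); } while (x >= limit);
  return (int)(x % (uint64_t)n);
}

static double joint_entropy(const std::vector<int> &bx,
                            const std::vector<int> &by,
                            int b, std::vector<int> &cnt) {
  std::fill(cnt.begin(), cnt.end(), 0);
  const int n = bx.size();
  for (int i = 0; i < n; ++i) cnt[bx[i] * b + by[i]]++;
  double h = 0.0;
  for (int c = 0; c < b * b; ++c) {
    if (cnt[c] > 0) {
      double p = (double)cnt[c] / n;
      h -= p * std::log(p);
    }
  }
  return h;
}

static double marginal_entropy(const std::vector<int> &bx, int b) {
  std::vector<int> cnt(b, 0);
  for (size_t i = 0; i < bx.size(); ++i) cnt[bx[i]]++;
  double h = 0.0;
  for (int c = 0; c < b; ++c) {
    if (cnt[c] > 0) {
      double p = (double)cnt[c] / bx.size();
      h -= p * std::log(p);
    }
  }
  return h;
}

// [[Rcpp::export(name = ".mi_pair_cpp")]]
double mi_pair_cpp(IntegerVector bx, IntegerVector by, int b) {
  int n = bx.size();
  std::vector<int> vx(bx.begin(), bx.end()), vy(by.begin(), by.end());
  std::vector<int> cnt(b * b);
  double h = joint_entropy(vx, vy, b, cnt);
  return marginal_entropy(vx, b) + marginal_entropy(vy, b) - h;
}

// All-pairs mutual information with per-pair permutation p-values.
// bins: n x K matrix of 0-based bin indices; B permutations; seed drives
// a per-pair splitmix64 stream.
// [[Rcpp::export(name = ".mi_perm_all_cpp")]]
List mi_perm_all_cpp(IntegerMatrix bins, int b, int B, double seed) {
  const int n = bins.nrow(), K = bins.ncol();
  NumericMatrix mi(K, K), pval(K, K);
  std::vector<int> cnt(b * b);
  std::vector<std::vector<int>> cols(K, std::vector<int>(n));
  std::vector<double> hx(K);
  for (int j = 0; j < K; ++j) {
    for (int i = 0; i < n; ++i) cols[j][i] = bins(i, j);
    hx[j] = marginal_entropy(cols[j], b);
  }
  std::vector<int> perm(n);
  const uint64_t base = (uint64_t)seed;
  for (int a = 0; a < K; ++a) {
    mi(a, a) = 0.0; pval(a, a) = 1.0;
    for (int c = a + 1; c < K; ++c) {
      double hxy = joint_entropy(cols[a], cols[c], b, cnt);
      double mi_obs = hx[a] + hx[c] - hxy;
      mi(a, c) = mi(c, a) = mi_obs;
      if (B > 0) {
        uint64_t state = base ^ (0x100000001ULL * (uint64_t)(a * K + c + 1));
        perm = cols[c];
        int worse = 0;
        for (int rep = 0; rep < B; ++rep) {
          // Fisher-Yates shuffle
          for (int i = n - 1; i > 0; --i) {
            int k = rand_below(state, i + 1);
            std::swap(perm[i], perm[k]);
          }
          double h = joint_entropy(cols[a], perm, b, cnt);
          double mi_p = hx[a] + hx[c] - h;
          if (mi_p >= mi_obs - 1e-12) worse++;
        }
        pval(a, c) = pval(c, a) = (1.0 + worse) / (B + 1.0);
      } else {
        pval(a, c) = pval(c, a) = NA_REAL;
      }
    }
  }
  return List::create(_["mi"] = mi, _["p"] = pval);
}
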