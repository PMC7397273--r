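#include <Rcpp.h>
#include <unordered_map>
#include <unordered_set>
#include <vector>
#include <array>
#include <cstdint>
#include <algorithm>

using namespace Rcpp;

// Maximal repeated pairs of four orientation types under a Hamming mismatch
// budget. Each orientation reduces to plain forward matching between the
// genome A and a transformed copy B (identity / complement / reversal /
// reverse complement), so every candidate pair lies on one diagonal of the
// (A, B) comparison. Exact k-mer seeds (pigeonhole-safe:
// k <= min_len / (max_mm + 1)) locate candidate diagonals; around each seed
// cluster the diagonal is explored just past the (max_mm + 1)-th mismatch on
// either side, and all maximal windows with <= max_mm mismatches and length
// >= min_len are enumerated from the mismatch positions. Any qualifying
// window contains an exact run >= k, so seed exploration is exhaustive.
// N never matches anything, including another N.

static const int TYPE_FORWARD = 0;
static const int TYPE_REVERSE = 1;
static const int TYPE_PALINDROMIC = 2;
static const int TYPE_COMPLEMENT = 3;

static inline int comp_code(int c) {
  switch (c) {  // A<->T, C<->G, N stays N
  case 0: return 3;
  case 1: return 2;
  case 2: return 1;
  case 3: return 0;
  default: return 4;
  }
}

struct HitKey {
  int type, p1, p2, len;
  bool operator==(const HitKey& o) const {
    return type == o.type && p1 == o.p1 && p2 == o.p2 && len == o.len;
  }
};
struct HitKeyHash {
  std::size_t operator()(const HitKey& k) const {
    std::size_t h = (std::size_t)k.type;
    h = h * 1000003u + (std::size_t)k.p1;
    h = h * 1000003u + (std::size_t)k.p2;
    h = h * 1000003u + (std::size_t)k.len;
    return h;
  }
};

struct HitRec {
  int type, p1, p2, len, mm;
};

// Emit maximal windows from the sentinel list S (bounds + interior
// mismatch positions, ascending). S.front()/S.back() are either mismatch
// positions or out-of-range boundary sentinels; interior entries are
// mismatches. A window spans (S[a], S[a + max_mm + 1]) exclusive.
static void emit_windows(const std::vector<int>& S, int min_len, int max_mm,
                         std::vector<std::array<int, 3> >& out) {
  int T = (int)S.size() - 2;  // interior mismatches
  int a_max = T > max_mm ? T - max_mm : 0;
  for (int a = 0; a <= a_max; ++a) {
    int ridx = a + max_mm + 1;
    if (ridx > T + 1) ridx = T + 1;
    int left = S[a], right = S[ridx];
    int len = right - left - 1;
    if (len < min_len) continue;
    int nmm = ridx - a - 1;
    out.push_back({left + 1, len, nmm});
  }
}

// [[Rcpp::export]]
DataFrame find_repeats_cpp(IntegerVector seq_codes, int min_len, int max_mm,
                           LogicalVector types) {
  int n = seq_codes.size();
  std::vector<int> A(seq_codes.begin(), seq_codes.end());

  int k = min_len / (max_mm + 1);
  if (k < 1) k = 1;
  if (k > 31) k = 31;
  uint64_t mask = (k == 31) ? ((~0ULL) >> 2) : ((1ULL << (2 * k)) - 1);

  // k-mer index of A (windows containing N are skipped)
  std::unordered_map<uint64_t, std::vector<int> > index;
  if (n >= k) {
    uint64_t h = 0;
    int run = 0;
    for (int i = 0; i < n; ++i) {
      int c = A[i];
      if (c > 3) { run = 0; h = 0; continue; }
      h = ((h << 2) | (uint64_t)c) & mask;
      if (++run >= k) index[h].emplace_back(i - k + 1);
    }
  }

  std::unordered_set<HitKey, HitKeyHash> seen;
  std::vector<HitRec> hits;

  for (int type = 0; type < 4; ++type) {
    if (!types[type]) continue;
    std::vector<int> B(n);
    for (int j = 0; j < n; ++j) {
      switch (type) {
      case TYPE_FORWARD: B[j] = A[j]; break;
      case TYPE_COMPLEMENT: B[j] = comp_code(A[j]); break;
      case TYPE_REVERSE: B[j] = A[n - 1 - j]; break;
      default: B[j] = comp_code(A[n - 1 - j]); break;
      }
    }
    // seed positions (A-coordinate of window start) grouped by diagonal
    std::unordered_map<int, std::vector<int> > diag_seeds;
    if (n >= k && n >= min_len) {
      uint64_t h = 0;
      int run = 0;
      for (int j = 0; j < n; ++j) {
        int c = B[j];
        if (c > 3) { run = 0; h = 0; continue; }
        h = ((h << 2) | (uint64_t)c) & mask;
        if (++run >= k) {
          auto it = index.find(h);
          if (it != index.end()) {
            int js = j - k + 1;
            for (int is : it->second) diag_seeds[js - is].emplace_back(is);
          }
        }
      }
    }

    std::vector<std::array<int, 3> > wins;
    std::vector<int> S;
    for (auto& kv : diag_seeds) {
      int d = kv.first;
      if ((type == TYPE_FORWARD || type == TYPE_COMPLEMENT) && d == 0) continue;
      int lo = std::max(0, -d);
      int hi = std::min(n - 1, n - 1 - d);
      if (hi - lo + 1 < min_len) continue;
      std::vector<int>& seeds = kv.second;
      std::sort(seeds.begin(), seeds.end());
      seeds.erase(std::unique(seeds.begin(), seeds.end()), seeds.end());
      wins.clear();

      std::size_t idx = 0;
      while (idx < seeds.size()) {
        int s = seeds[idx];
        // walk left collecting up to max_mm + 1 mismatches
        std::vector<int> ML;
        int pos = s - 1;
        while (pos >= lo && (int)ML.size() < max_mm + 1) {
          int a = A[pos], b = B[pos + d];
          if (a > 3 || b > 3 || a != b) ML.push_back(pos);
          --pos;
        }
        bool left_is_mm = ((int)ML.size() == max_mm + 1);
        int eL = left_is_mm ? ML.back() : lo - 1;
        // walk right, consuming further seeds; stop max_mm + 1 mismatches
        // past the last seed consumed
        std::vector<int> MR;
        int cnt_after = 0;
        int eR;
        pos = s + k;
        for (;;) {
          while (idx + 1 < seeds.size() && seeds[idx + 1] <= pos) {
            ++idx;
            cnt_after = 0;  // seed spans are exact matches
          }
          if (pos > hi) { eR = hi + 1; break; }
          int a = A[pos], b = B[pos + d];
          if (a > 3 || b > 3 || a != b) {
            MR.push_back(pos);
            if (++cnt_after == max_mm + 1) { eR = pos; break; }
          }
          ++pos;
        }
        bool right_is_mm = (eR <= hi);
        // sentinel list: eL, interior mismatches ascending, eR
        S.clear();
        S.push_back(eL);
        for (int t = (int)ML.size() - (left_is_mm ? 2 : 1); t >= 0; --t)
          S.push_back(ML[t]);
        int mr_n = (int)MR.size() - (right_is_mm ? 1 : 0);
        for (int t = 0; t < mr_n; ++t) S.push_back(MR[t]);
        S.push_back(eR);
        emit_windows(S, min_len, max_mm, wins);
        ++idx;
      }

      for (auto& w : wins) {
        int i_start = w[0], len = w[1], nmm = w[2];
        int j_start = i_start + d;
        int p1 = i_start, p2;
        if (type == TYPE_FORWARD || type == TYPE_COMPLEMENT) {
          p2 = j_start;
        } else {
          p2 = n - j_start - len;
        }
        if (p1 > p2) std::swap(p1, p2);
        if ((type == TYPE_FORWARD || type == TYPE_COMPLEMENT) && p1 == p2)
          continue;
        HitKey key{type, p1, p2, len};
        if (seen.insert(key).second) hits.push_back({type, p1, p2, len, nmm});
      }
    }
  }

  int m = (int)hits.size();
  IntegerVector rt(m), p1(m), p2(m), len(m), mm(m);
  for (int i = 0; i < m; ++i) {
    rt[i] = hits[i].type + 1;
    p1[i] = hits[i].p1;
    p2[i] = hits[i].p2;
    len[i] = hits[i].len;
    mm[i] = hits[i].mm;
  }
  return DataFrame::create(_["rtype_code"] = rt, _["pos1"] = p1,
                           _["pos2"] = p2, _["length"] = len,
                           _["mismatches"] = mm);
}
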