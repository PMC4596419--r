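// Fragment-based ANI core: k-mer seeded window location plus banded
// semi-global alignment (fragment global, window ends free). Deterministic:
// ties among candidate windows break toward the leftmost subject position.

#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <string>
#include <cstdint>

using namespace Rcpp;

static inline int enc(char c) {
  switch (c) {
  case 'A': return 0;
  case 'C': return 1;
  case 'G': return 2;
  case 'T': return 3;
  default:  return 4;  // N or other
  }
}

// Banded semi-global alignment of fragment a (global) inside window b
// (free end gaps in b). Band: for fragment row i, window columns
// j in [i, i + 2*band]. Scoring: match +2, mismatch -3, gap -5 (linear).
// N never matches. Fills identity stats via traceback.
struct AlnStats {
  int identical;   // identical aligned columns
  int columns;     // total alignment columns (incl. gap columns)
  int covered;     // fragment positions aligned against a window base
};

static AlnStats banded_fit(const std::string& a, const std::string& b, int band) {
  const int m = (int)a.size();
  const int n = (int)b.size();
  const int W = 2 * band + 1;
  const int NEG = -1000000000;
  const int MATCH = 2, MISMATCH = -3, GAP = -5;

  // dp[i][k] with k = j - i, j in [i, i+2*band] -> k in [0, 2*band]
  std::vector<int> prev(W, NEG), cur(W, NEG);
  std::vector<signed char> tb((size_t)(m + 1) * W, 0); // 1=diag 2=up(gap in b col) 3=left(gap in a)

  // row 0: leading window gap is free
  for (int k = 0; k < W; ++k) {
    int j = k; // i = 0
    prev[k] = (j <= n) ? 0 : NEG;
  }
  for (int i = 1; i <= m; ++i) {
    int ca = enc(a[i - 1]);
    for (int k = 0; k < W; ++k) cur[k] = NEG;
    for (int k = 0; k < W; ++k) {
      int j = i + k;
      if (j > n) break;
      int best = NEG; signed char dir = 0;
      if (j >= 1) { // diagonal from (i-1, j-1): same k
        int s = prev[k];
        if (s > NEG) {
          int cb = enc(b[j - 1]);
          int sc = s + ((ca == cb && ca < 4) ? MATCH : MISMATCH);
          if (sc > best) { best = sc; dir = 1; }
        }
      }
      // up: from (i-1, j): k' = j - (i-1) = k + 1
      if (k + 1 < W && prev[k + 1] > NEG) {
        int sc = prev[k + 1] + GAP;
        if (sc > best) { best = sc; dir = 2; }
      }
      // left: from (i, j-1): k' = k - 1
      if (k - 1 >= 0 && cur[k - 1] > NEG) {
        int sc = cur[k - 1] + GAP;
        if (sc > best) { best = sc; dir = 3; }
      }
      cur[k] = best;
      tb[(size_t)i * W + k] = dir;
    }
    std::swap(prev, cur);
  }
  // best end: max over k of dp[m][k]; trailing window gap free
  int bestk = -1, bestsc = NEG;
  for (int k = 0; k < W; ++k) {
    int j = m + k;
    if (j > n) break;
    if (prev[k] > bestsc) { bestsc = prev[k]; bestk = k; }
  }
  AlnStats st{0, 0, 0};
  if (bestk < 0) return st;
  int i = m, k = bestk;
  while (i > 0) {
    signed char dir = tb[(size_t)i * W + k];
    if (dir == 1) {
      int j = i + k;
      int ca = enc(a[i - 1]), cb = enc(b[j - 1]);
      if (ca == cb && ca < 4) st.identical++;
      st.covered++;
      st.columns++;
      i--; // k unchanged
    } else if (dir == 2) {
      st.columns++;
      i--; k++;
    } else if (dir == 3) {
      st.columns++;
      k--;
    } else {
      break; // hit row-0 boundary
    }
  }
  return st;
}

// [[Rcpp::export(name = ".ani_fragments_cpp")]]
DataFrame ani_fragments_cpp(CharacterVector query_contigs,
                            std::string subject,
                            int frag_len = 1020,
                            int k = 15,
                            int band = 51,
                            int seed_step = 1) {
  // index subject k-mers (2-bit packed; k <= 15 fits in 32 bits)
  const uint64_t mask = (k >= 32) ? ~0ULL : ((1ULL << (2 * k)) - 1ULL);
  std::unordered_map<uint64_t, std::vector<int>> index;
  index.reserve(subject.size());
  {
    uint64_t key = 0; int run = 0;
    for (int p = 0; p < (int)subject.size(); ++p) {
      int c = enc(subject[p]);
      if (c >= 4) { run = 0; key = 0; continue; }
      key = ((key << 2) | (uint64_t)c) & mask;
      if (++run >= k) index[key].push_back(p - k + 1);
    }
  }
  std::vector<int> frag_contig, frag_start, sub_start;
  std::vector<double> identity, coverage;
  std::vector<int> identical_cols, aligned_cols;

  for (int ci = 0; ci < query_contigs.size(); ++ci) {
    std::string ctg = as<std::string>(query_contigs[ci]);
    int nfrag = (int)ctg.size() / frag_len;  // tail discarded
    for (int f = 0; f < nfrag; ++f) {
      std::string frag = ctg.substr((size_t)f * frag_len, frag_len);
      // vote for candidate subject start positions
      std::unordered_map<int, int> votes;
      uint64_t key = 0; int run = 0;
      for (int p = 0; p < frag_len; ++p) {
        int c = enc(frag[p]);
        if (c >= 4) { run = 0; key = 0; continue; }
        key = ((key << 2) | (uint64_t)c) & mask;
        if (run + 1 >= k && ((p - k + 1) % seed_step == 0)) {
          auto it = index.find(key);
          if (it != index.end() && it->second.size() <= 64) {
            for (int s : it->second) votes[s - (p - k + 1)]++;
          }
        }
        ++run;
      }
      int best_start = -1, best_votes = 0;
      for (auto& kv : votes) {
        if (kv.second > best_votes ||
            (kv.second == best_votes && best_start >= 0 && kv.first < best_start)) {
          best_votes = kv.second;
          best_start = kv.first;
        }
      }
      frag_contig.push_back(ci + 1);
      frag_start.push_back(f * frag_len + 1);
      if (best_start < 0) {  // no seed support: unalignable fragment
        sub_start.push_back(NA_INTEGER);
        identity.push_back(0.0); coverage.push_back(0.0);
        identical_cols.push_back(0); aligned_cols.push_back(0);
        continue;
      }
      int ws = best_start - band;
      int we = best_start + frag_len + band;  // exclusive
      if (ws < 0) ws = 0;
      if (we > (int)subject.size()) we = (int)subject.size();
      std::string window = subject.substr(ws, we - ws);
      // fragment starts at offset (best_start - ws) in window, which lies in
      // [0, band]; the band j in [i, i + 2*band] always contains it
      AlnStats st = banded_fit(frag, window, band);
      if (st.columns == 0) {
        sub_start.push_back(NA_INTEGER);
        identity.push_back(0.0); coverage.push_back(0.0);
        identical_cols.push_back(0); aligned_cols.push_back(0);
        continue;
      }
      sub_start.push_back(best_start + 1);
      identity.push_back((double)st.identical / (double)st.columns);
      coverage.push_back((double)st.covered / (double)frag_len);
      identical_cols.push_back(st.identical);
      aligned_cols.push_back(st.columns);
    }
  }
  return DataFrame::create(
    _["contig"] = frag_contig,
    _["frag_start"] = frag_start,
    _["subject_start"] = sub_start,
    _["identity"] = identity,
    _["coverage"] = coverage,
    _["identical_cols"] = identical_cols,
    _["aligned_cols"] = aligned_cols
  );
}

// Longest strictly increasing subsequence length (patience sorting).
// [[Rcpp::export(name = ".lis_length_cpp")]]
int lis_length_cpp(NumericVector x) {
  std::vector<double> tails;
  for (double v : x) {
    auto it = std::lower_bound(tails.begin(), tails.end(), v);
    if (it == tails.end()) tails.push_back(v);
    else *it = v;
  }
  return (int)tails.size();
}
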