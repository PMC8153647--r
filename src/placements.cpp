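#include <Rcpp.h>
#include <unordered_set>
#include <algorithm>
#include <cstdint>
using namespace Rcpp;

// Genome index: 2-bit-ish encoded chromosomes (N -> 4, always a mismatch)
// plus a CSR table of all exact 6-mer seed positions in global coordinates.
// Seeded search is pigeonhole-complete: a pattern split into (max_mm + 1)
// blocks has at least one error-free block, whose leading 6-mer hits the
// table exactly, provided pattern length >= 6 * (max_mm + 1); shorter
// patterns fall back to a full scan.

static const int SEED_K = 6;
static const int SEED_SPACE = 4096; // 4^6

struct GenomeIndex {
  std::vector<std::string> names;
  std::vector<std::vector<uint8_t>> seqs;
  std::vector<long long> offsets; // global start per chrom, plus total at end
  std::vector<int> seed_start;    // CSR offsets, SEED_SPACE + 1
  std::vector<long long> seed_pos;
};

static inline uint8_t enc_base(char c) {
  switch (c) {
    case 'A': case 'a': return 0;
    case 'C': case 'c': return 1;
    case 'G': case 'g': return 2;
    case 'T': case 't': return 3;
    default: return 4;
  }
}

static std::vector<uint8_t> enc_seq(const std::string& s) {
  std::vector<uint8_t> v(s.size());
  for (size_t i = 0; i < s.size(); ++i) v[i] = enc_base(s[i]);
  return v;
}

// [[Rcpp::export]]
SEXP cpp_build_index(CharacterVector seqs, CharacterVector names) {
  GenomeIndex* gi = new GenomeIndex();
  long long off = 0;
  for (int i = 0; i < seqs.size(); ++i) {
    gi->names.push_back(as<std::string>(names[i]));
    std::string s = as<std::string>(seqs[i]);
    gi->offsets.push_back(off);
    gi->seqs.push_back(enc_seq(s));
    off += (long long)s.size();
  }
  gi->offsets.push_back(off);

  // count 6-mers, then fill CSR
  std::vector<int> counts(SEED_SPACE, 0);
  for (size_t c = 0; c < gi->seqs.size(); ++c) {
    const std::vector<uint8_t>& sq = gi->seqs[c];
    if ((int)sq.size() < SEED_K) continue;
    int code = 0, bad = 0;
    for (int i = 0; i < (int)sq.size(); ++i) {
      code = ((code << 2) | (sq[i] & 3)) & (SEED_SPACE - 1);
      if (sq[i] > 3) bad = SEED_K; else if (bad > 0) --bad;
      if (i >= SEED_K - 1 && bad == 0) counts[code]++;
    }
  }
  gi->seed_start.assign(SEED_SPACE + 1, 0);
  for (int k = 0; k < SEED_SPACE; ++k) gi->seed_start[k + 1] = gi->seed_start[k] + counts[k];
  gi->seed_pos.assign(gi->seed_start[SEED_SPACE], 0);
  std::vector<int> fill(gi->seed_start.begin(), gi->seed_start.end() - 1);
  for (size_t c = 0; c < gi->seqs.size(); ++c) {
    const std::vector<uint8_t>& sq = gi->seqs[c];
    if ((int)sq.size() < SEED_K) continue;
    long long base = gi->offsets[c];
    int code = 0, bad = 0;
    for (int i = 0; i < (int)sq.size(); ++i) {
      code = ((code << 2) | (sq[i] & 3)) & (SEED_SPACE - 1);
      if (sq[i] > 3) bad = SEED_K; else if (bad > 0) --bad;
      if (i >= SEED_K - 1 && bad == 0)
        gi->seed_pos[fill[code]++] = base + (i - SEED_K + 1);
    }
  }
  XPtr<GenomeIndex> ptr(gi, true);
  return ptr;
}

static inline int chrom_of(const GenomeIndex* gi, long long gpos) {
  // index of chromosome containing global position gpos
  int lo = 0, hi = (int)gi->seqs.size() - 1;
  while (lo < hi) {
    int mid = (lo + hi + 1) / 2;
    if (gi->offsets[mid] <= gpos) lo = mid; else hi = mid - 1;
  }
  return lo;
}

static inline int verify_at(const std::vector<uint8_t>& sq, int start,
                            const std::vector<uint8_t>& pat, int max_mm) {
  // mismatch count of pat aligned at start, early exit above max_mm
  int mm = 0;
  for (size_t i = 0; i < pat.size(); ++i) {
    uint8_t a = sq[start + i], b = pat[i];
    if (a > 3 || b > 3 || a != b) { if (++mm > max_mm) return -1; }
  }
  return mm;
}

static void placements_one(const GenomeIndex* gi, const std::vector<uint8_t>& pat,
                           int max_mm, std::vector<int>& out_chrom,
                           std::vector<int>& out_start, std::vector<int>& out_mm) {
  int P = (int)pat.size();
  int blocks = max_mm + 1;
  if (P >= SEED_K * blocks) {
    std::unordered_set<long long> seen;
    for (int b = 0; b < blocks; ++b) {
      int off = (int)((long long)b * P / blocks);
      int code = 0; bool ok = true;
      for (int j = 0; j < SEED_K; ++j) {
        if (pat[off + j] > 3) { ok = false; break; }
        code = (code << 2) | pat[off + j];
      }
      if (!ok) continue;
      for (int k = gi->seed_start[code]; k < gi->seed_start[code + 1]; ++k) {
        long long gstart = gi->seed_pos[k] - off;
        if (gstart < 0) continue;
        int c = chrom_of(gi, gstart);
        long long local = gstart - gi->offsets[c];
        if (local + P > (long long)gi->seqs[c].size()) continue;
        if (!seen.insert(gstart).second) continue;
        int mm = verify_at(gi->seqs[c], (int)local, pat, max_mm);
        if (mm >= 0) {
          out_chrom.push_back(c + 1);
          out_start.push_back((int)local);
          out_mm.push_back(mm);
        }
      }
    }
  } else {
    for (size_t c = 0; c < gi->seqs.size(); ++c) {
      int n = (int)gi->seqs[c].size();
      for (int s = 0; s + P <= n; ++s) {
        int mm = verify_at(gi->seqs[c], s, pat, max_mm);
        if (mm >= 0) {
          out_chrom.push_back((int)c + 1);
          out_start.push_back(s);
          out_mm.push_back(mm);
        }
      }
    }
  }
}

// [[Rcpp::export]]
DataFrame cpp_placements(SEXP idx, std::string pattern, int max_mm) {
  XPtr<GenomeIndex> gi(idx);
  std::vector<uint8_t> pat = enc_seq(pattern);
  std::vector<int> ch, st, mm;
  placements_one(gi.get(), pat, max_mm, ch, st, mm);
  return DataFrame::create(_["chrom"] = ch, _["start"] = st, _["mismatches"] = mm);
}

static std::string revcomp(const std::string& s) {
  std::string r(s.rbegin(), s.rend());
  for (auto& c : r) {
    switch (c) {
      case 'A': c = 'T'; break; case 'T': c = 'A'; break;
      case 'C': c = 'G'; break; case 'G': c = 'C'; break;
      default: c = 'N';
    }
  }
  return r;
}

// Batch end-to-end mapping of reads in both orientations; returns the best
// placement per read (min mismatches, forward orientation preferred on tie)
// and the total number of valid placements across both orientations.
// [[Rcpp::export]]
DataFrame cpp_map_linear_batch(SEXP idx, CharacterVector reads, int max_mm) {
  XPtr<GenomeIndex> gi(idx);
  int n = reads.size();
  LogicalVector mapped(n);
  IntegerVector chrom(n, NA_INTEGER), start(n, NA_INTEGER), mmv(n, NA_INTEGER), nhits(n, 0);
  CharacterVector ori(n, NA_STRING);
  for (int i = 0; i < n; ++i) {
    std::string rd = as<std::string>(reads[i]);
    std::vector<uint8_t> fw = enc_seq(rd), rv = enc_seq(revcomp(rd));
    std::vector<int> ch, st, mm;
    placements_one(gi.get(), fw, max_mm, ch, st, mm);
    int nf = (int)ch.size();
    placements_one(gi.get(), rv, max_mm, ch, st, mm);
    nhits[i] = (int)ch.size();
    if (ch.empty()) { mapped[i] = false; continue; }
    int best = 0;
    for (int k = 1; k < (int)ch.size(); ++k) if (mm[k] < mm[best]) best = k;
    mapped[i] = true;
    chrom[i] = ch[best]; start[i] = st[best]; mmv[i] = mm[best];
    ori[i] = best < nf ? "fwd" : "rev";
  }
  return DataFrame::create(_["mapped"] = mapped, _["chrom"] = chrom,
                           _["start"] = start, _["orientation"] = ori,
                           _["mismatches"] = mmv, _["n_hits"] = nhits);
}

// Per-position mismatch indicator of pattern aligned at gstart (0-based)
// on chromosome `chrom` (1-based); out-of-range positions count mismatched.
// [[Rcpp::export]]
IntegerVector cpp_diag_mismatch(SEXP idx, int chrom, int gstart, std::string pattern) {
  XPtr<GenomeIndex> gi(idx);
  const std::vector<uint8_t>& sq = gi->seqs[chrom - 1];
  std::vector<uint8_t> pat = enc_seq(pattern);
  IntegerVector out(pat.size());
  for (size_t i = 0; i < pat.size(); ++i) {
    long long p = (long long)gstart + (long long)i;
    if (p < 0 || p >= (long long)sq.size()) { out[i] = 1; continue; }
    uint8_t a = sq[p], b = pat[i];
    out[i] = (a > 3 || b > 3 || a != b) ? 1 : 0;
  }
  return out;
}

// Exact two-sided rank-sum p-value by dynamic programming over the count
// distribution of subset sums of doubled midranks.  Identical to full
// enumeration of all C(n, n1) group assignments.
// ranks2: 2 * midranks of the pooled sample (integers); w2_obs: 2 * rank
// sum of group A.
// [[Rcpp::export]]
double cpp_ranksum_exact_p(IntegerVector ranks2, int n1, double w2_obs) {
  int n = ranks2.size();
  long long maxsum = 0;
  for (int i = 0; i < n; ++i) maxsum += ranks2[i];
  std::vector<std::vector<double>> dp(n1 + 1, std::vector<double>(maxsum + 1, 0.0));
  dp[0][0] = 1.0;
  long long run = 0;
  for (int i = 0; i < n; ++i) {
    int v = ranks2[i];
    run += v;
    int kmax = std::min(n1, i + 1);
    for (int k = kmax; k >= 1; --k) {
      long long smax = std::min(run, maxsum);
      for (long long s = smax; s >= v; --s)
        if (dp[k - 1][s - v] > 0) dp[k][s] += dp[k - 1][s - v];
    }
  }
  double total = 0.0, extreme = 0.0;
  double mu = (double)n1 * (double)maxsum / (double)n;
  double dev = std::abs(w2_obs - mu) - 1e-9;
  for (long long s = 0; s <= maxsum; ++s) {
    double c = dp[n1][s];
    if (c == 0) continue;
    total += c;
    if (std::abs((double)s - mu) >= dev) extreme += c;
  }
  return extreme / total;
}

// Longest common substring between `a` and reverse-complement of `b`.
// Returns (length, end position in a, end position in rc(b)), 1-based ends;
// length 0 when no common base.
// [[Rcpp::export]]
IntegerVector cpp_longest_rc_match(std::string a, std::string b) {
  std::string brc = revcomp(b);
  int n = (int)a.size(), m = (int)brc.size();
  std::vector<int> prev(m + 1, 0), cur(m + 1, 0);
  int best = 0, bi = 0, bj = 0;
  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      char x = a[i - 1], y = brc[j - 1];
      if (x == y && x != 'N') {
        cur[j] = prev[j - 1] + 1;
        if (cur[j] > best) { best = cur[j]; bi = i; bj = j; }
      } else cur[j] = 0;
    }
    std::swap(prev, cur);
  }
  return IntegerVector::create(best, bi, bj);
}
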