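// Compiled kernels: small RNA tag placement (<=2 substitutions plus at most
// one 1-2 nt microindel) and Nussinov maximum base pairing.
//
// The aligner is seed-and-extend: each tag is split into four blocks; any
// qualifying placement leaves at least one block event-free, so its leading
// 4-mer occurs exactly in the genome at an offset within +/- indel length of
// the placement start. Candidates from a 4-mer index are then verified
// directly against the definition of a valid placement.

#include <Rcpp.h>
#include <cstdint>
#include <vector>
#include <string>
using namespace Rcpp;

static inline int base_code(char c) {
  switch (c) {
  case 'A': case 'a': return 0;
  case 'C': case 'c': return 1;
  case 'G': case 'g': return 2;
  case 'T': case 't': return 3;
  default: return 4;  // N and friends: never match
  }
}

static std::vector<uint8_t> encode(const std::string& s) {
  std::vector<uint8_t> v(s.size());
  for (size_t i = 0; i < s.size(); ++i) v[i] = (uint8_t)base_code(s[i]);
  return v;
}

static std::vector<uint8_t> revcomp_codes(const std::vector<uint8_t>& v) {
  std::vector<uint8_t> r(v.size());
  for (size_t i = 0; i < v.size(); ++i) {
    uint8_t c = v[v.size() - 1 - i];
    r[i] = (c < 4) ? (uint8_t)(3 - c) : (uint8_t)4;
  }
  return r;
}

// mismatches with early abort; positions with code 4 always mismatch
static inline int mm_count(const std::vector<uint8_t>& S, size_t s,
                           const std::vector<uint8_t>& t, size_t from,
                           size_t to, int budget) {
  int mm = 0;
  for (size_t i = from; i < to; ++i) {
    uint8_t a = S[s + i], b = t[i];
    if (a != b || a > 3) { if (++mm > budget) return mm; }
  }
  return mm;
}

struct Hit { int start; int span; int mm; int indel; };

// verify candidate start s for tag t on contig S; returns best hit or mm<0
static Hit verify(const std::vector<uint8_t>& S, long s,
                  const std::vector<uint8_t>& t, int max_mm, int max_indel) {
  Hit best; best.mm = -1; best.indel = 0; best.start = (int)s; best.span = 0;
  const long N = (long)S.size(), L = (long)t.size();
  if (s < 0) return best;
  // exact span (no indel)
  if (s + L <= N) {
    int mm = mm_count(S, s, t, 0, L, max_mm);
    if (mm <= max_mm) { best.mm = mm; best.span = (int)L; return best; }
  }
  for (int d = 1; d <= max_indel; ++d) {
    // genome carries d extra bases after breakpoint g (tag-relative)
    if (s + L + d <= N) {
      std::vector<int> suf(L + 1, 0);
      for (long i = L - 1; i >= 0; --i) {
        uint8_t a = S[s + i + d], b = t[i];
        suf[i] = suf[i + 1] + ((a != b || a > 3) ? 1 : 0);
      }
      int pm = 0;
      for (long g = 1; g <= L - 1 && pm <= max_mm; ++g) {
        uint8_t a = S[s + g - 1], b = t[g - 1];
        if (a != b || a > 3) ++pm;
        if (pm > max_mm) break;
        int tot = pm + suf[g];
        if (tot <= max_mm &&
            (best.mm < 0 || tot < best.mm ||
             (tot == best.mm && d < best.indel))) {
          best.mm = tot; best.indel = d; best.span = (int)(L + d);
        }
      }
    }
    // genome lacks d bases: d tag bases unaligned at breakpoint g
    if (s + L - d <= N && L - d >= 2) {
      std::vector<int> suf(L + 1, 0);
      for (long i = L - 1; i >= d; --i) {
        uint8_t a = S[s + i - d], b = t[i];
        suf[i] = suf[i + 1] + ((a != b || a > 3) ? 1 : 0);
      }
      int pm = 0;
      for (long g = 1; g <= L - d - 1 && pm <= max_mm; ++g) {
        uint8_t a = S[s + g - 1], b = t[g - 1];
        if (a != b || a > 3) ++pm;
        if (pm > max_mm) break;
        int tot = pm + suf[g + d];
        if (tot <= max_mm &&
            (best.mm < 0 || tot < best.mm ||
             (tot == best.mm && d < best.indel))) {
          best.mm = tot; best.indel = d; best.span = (int)(L - d);
        }
      }
    }
  }
  return best;
}

// [[Rcpp::export]]
DataFrame cpp_align_tags(CharacterVector contigs, CharacterVector tags,
                         int max_mm, int max_indel) {
  const int K = 4, NKEY = 256;
  int nc = contigs.size(), nt = tags.size();
  std::vector<std::vector<uint8_t>> genomes(nc);
  std::vector<std::vector<int>> bucket_start(nc), bucket_pos(nc);
  for (int c = 0; c < nc; ++c) {
    genomes[c] = encode(as<std::string>(contigs[c]));
    const std::vector<uint8_t>& S = genomes[c];
    long N = (long)S.size();
    std::vector<int> cnt(NKEY + 1, 0);
    std::vector<int> keys(N > K ? N - K + 1 : 0, -1);
    for (long p = 0; p + K <= N; ++p) {
      if (S[p] > 3 || S[p + 1] > 3 || S[p + 2] > 3 || S[p + 3] > 3) continue;
      keys[p] = (S[p] << 6) | (S[p + 1] << 4) | (S[p + 2] << 2) | S[p + 3];
      cnt[keys[p] + 1]++;
    }
    for (int k = 0; k < NKEY; ++k) cnt[k + 1] += cnt[k];
    std::vector<int> pos(cnt[NKEY]);
    std::vector<int> fill(cnt.begin(), cnt.end() - 1);
    for (long p = 0; p + K <= N; ++p)
      if (keys[p] >= 0) pos[fill[keys[p]]++] = (int)p;
    bucket_start[c] = cnt;
    bucket_pos[c] = pos;
  }

  std::vector<int> r_tag, r_contig, r_start, r_end, r_mm, r_indel;
  std::vector<std::string> r_strand;

  for (int ti = 0; ti < nt; ++ti) {
    std::string tseq = as<std::string>(tags[ti]);
    std::vector<uint8_t> fw = encode(tseq);
    long L = (long)fw.size();
    if (L < 16) stop("align_tags: tag shorter than 16 nt");
    std::vector<uint8_t> rv = revcomp_codes(fw);
    for (int c = 0; c < nc; ++c) {
      const std::vector<uint8_t>& S = genomes[c];
      long N = (long)S.size();
      if (N < L - max_indel) continue;
      for (int strand = 0; strand < 2; ++strand) {
        const std::vector<uint8_t>& t = strand ? rv : fw;
        // collect candidate starts
        std::vector<long> cand;
        long blk = L / 4;
        for (int b = 0; b < 4; ++b) {
          long tb = b * blk;
          int key = (t[tb] << 6) | (t[tb + 1] << 4) |
                    (t[tb + 2] << 2) | t[tb + 3];
          int lo = bucket_start[c][key], hi = bucket_start[c][key + 1];
          for (int q = lo; q < hi; ++q) {
            long s0 = (long)bucket_pos[c][q] - tb;
            for (int off = -max_indel; off <= max_indel; ++off)
              cand.push_back(s0 + off);
          }
        }
        std::sort(cand.begin(), cand.end());
        cand.erase(std::unique(cand.begin(), cand.end()), cand.end());
        for (long s : cand) {
          if (s < 0 || s >= N) continue;
          Hit h = verify(S, s, t, max_mm, max_indel);
          if (h.mm >= 0) {
            r_tag.push_back(ti + 1);
            r_contig.push_back(c + 1);
            r_strand.push_back(strand ? "-" : "+");
            r_start.push_back((int)s);
            r_end.push_back((int)s + h.span);
            r_mm.push_back(h.mm);
            r_indel.push_back(h.indel);
          }
        }
      }
    }
  }
  return DataFrame::create(_["tag"] = r_tag, _["contig"] = r_contig,
                           _["strand"] = r_strand, _["start"] = r_start,
                           _["end"] = r_end, _["mm"] = r_mm,
                           _["indel_len"] = r_indel,
                           _["stringsAsFactors"] = false);
}

// ---- Nussinov maximum base pairing ----------------------------------------

static inline bool can_pair(char a, char b) {
  int x = base_code(a), y = base_code(b);
  if (x > 3 || y > 3) return false;
  // Watson-Crick (A:T, G:C) plus G:U wobble (G:T in DNA alphabet)
  return (x + y == 3) || (x == 2 && y == 3) || (x == 3 && y == 2);
}

// Maximum non-crossing complementary pairing between arm A and arm B
// (B supplied 5'->3'; pairs are non-crossing when A runs forward and B
// backward, i.e. an alignment of A against reversed B scoring pairable
// positions, with unpaired bulges free). Nussinov recursion restricted to
// inter-arm pairs.
// [[Rcpp::export]]
int cpp_duplex_max_pairs(std::string armA, std::string armB) {
  int m = (int)armA.size(), n = (int)armB.size();
  std::string rb(armB.rbegin(), armB.rend());
  std::vector<std::vector<int>> D(m + 1, std::vector<int>(n + 1, 0));
  for (int i = 1; i <= m; ++i)
    for (int j = 1; j <= n; ++j) {
      int best = D[i - 1][j] > D[i][j - 1] ? D[i - 1][j] : D[i][j - 1];
      if (can_pair(armA[i - 1], rb[j - 1]) && D[i - 1][j - 1] + 1 > best)
        best = D[i - 1][j - 1] + 1;
      D[i][j] = best;
    }
  return D[m][n];
}

// [[Rcpp::export]]
List cpp_nussinov(std::string seq, int min_loop) {
  int n = (int)seq.size();
  if (n == 0) return List::create(_["n_pairs"] = 0,
                                  _["partner"] = IntegerVector(0));
  std::vector<std::vector<int>> M(n, std::vector<int>(n, 0));
  for (int len = min_loop + 2; len <= n; ++len) {
    for (int i = 0; i + len - 1 < n; ++i) {
      int j = i + len - 1;
      int best = M[i][j - 1];
      for (int k = i; k <= j - min_loop - 1; ++k) {
        if (!can_pair(seq[k], seq[j])) continue;
        int v = 1 + (k > i ? M[i][k - 1] : 0) +
                (k + 1 <= j - 1 ? M[k + 1][j - 1] : 0);
        if (v > best) best = v;
      }
      M[i][j] = best;
    }
  }
  IntegerVector partner(n, -1);
  std::vector<std::pair<int, int>> stack;
  stack.push_back(std::make_pair(0, n - 1));
  while (!stack.empty()) {
    int i = stack.back().first, j = stack.back().second;
    stack.pop_back();
    if (i >= j || j - i < min_loop + 1) continue;
    if (M[i][j] == M[i][j - 1]) { stack.push_back(std::make_pair(i, j - 1)); continue; }
    for (int k = i; k <= j - min_loop - 1; ++k) {
      if (!can_pair(seq[k], seq[j])) continue;
      int v = 1 + (k > i ? M[i][k - 1] : 0) +
              (k + 1 <= j - 1 ? M[k + 1][j - 1] : 0);
      if (v == M[i][j]) {
        partner[k] = j; partner[j] = k;
        if (k > i) stack.push_back(std::make_pair(i, k - 1));
        if (k + 1 <= j - 1) stack.push_back(std::make_pair(k + 1, j - 1));
        break;
      }
    }
  }
  return List::create(_["n_pairs"] = M[0][n - 1], _["partner"] = partner);
}
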