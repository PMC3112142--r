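#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <string>
#include <algorithm>
#include <cstdint>

using namespace Rcpp;

// Exhaustively-equivalent ungapped read mapper with a Hamming-distance budget.
//
// Every placement of a read (either strand) with at most `max_mm` mismatches is
// guaranteed to be examined: the read is split into max_mm + 1 non-overlapping
// chunks, so any placement within budget has at least one chunk matching the
// reference exactly (pigeonhole). Chunk hits are found through a k-mer prefix
// index of the reference; reads too short for k-length chunks fall back to a
// full scan over every offset. 'N' (or any non-ACGT character) mismatches
// every reference base, including 'N' itself.

static const int KIDX = 12;          // index k-mer length, 2 bits/base -> 24 bits

static inline int base_code(char c) {
  switch (c) {
    case 'A': return 0;
    case 'C': return 1;
    case 'G': return 2;
    case 'T': return 3;
    default:  return -1;
  }
}

static inline char comp_base(char c) {
  switch (c) {
    case 'A': return 'T';
    case 'C': return 'G';
    case 'G': return 'C';
    case 'T': return 'A';
    default:  return 'N';
  }
}

// Hamming distance with early exit; non-ACGT in either string always mismatches.
static inline int hamming_capped(const char *read, const char *ref, int len, int cap) {
  int mm = 0;
  for (int i = 0; i < len; ++i) {
    char r = read[i];
    if (r != ref[i] || base_code(r) < 0) {
      if (++mm > cap) return mm;
    }
  }
  return mm;
}

struct KmerIndex {
  // code -> positions; codes with ambiguous bases are skipped
  std::unordered_map<uint32_t, std::vector<int> > table;
  explicit KmerIndex(const std::string &ref) {
    int n = (int) ref.size();
    if (n < KIDX) return;
    table.reserve(n);
    uint32_t code = 0;
    int valid = 0;                   // consecutive valid bases ending at i
    const uint32_t mask = (1u << (2 * KIDX)) - 1u;
    for (int i = 0; i < n; ++i) {
      int b = base_code(ref[i]);
      if (b < 0) { valid = 0; code = 0; continue; }
      code = ((code << 2) | (uint32_t) b) & mask;
      if (++valid >= KIDX) table[code].push_back(i - KIDX + 1);
    }
  }
  const std::vector<int> *lookup(uint32_t code) const {
    std::unordered_map<uint32_t, std::vector<int> >::const_iterator it = table.find(code);
    return it == table.end() ? (const std::vector<int> *) 0 : &it->second;
  }
};

struct Best {
  int best_mm;       // minimal distance seen (<= cap), or cap+1 if none
  int best_pos;      // 0-based leftmost of first best placement
  int best_strand;   // 0 = '+', 1 = '-'
  int n_best;        // placements tying best_mm
  int n_hits;        // all placements with distance <= cap
  Best(int cap) : best_mm(cap + 1), best_pos(-1), best_strand(0), n_best(0), n_hits(0) {}
  void add(int mm, int pos, int strand) {
    ++n_hits;
    if (mm < best_mm) {
      best_mm = mm; best_pos = pos; best_strand = strand; n_best = 1;
    } else if (mm == best_mm) {
      ++n_best;
    }
  }
};

static void scan_all_offsets(const std::string &read, const std::string &ref,
                             int cap, int strand, Best &best) {
  int L = (int) read.size(), n = (int) ref.size();
  for (int o = 0; o + L <= n; ++o) {
    int mm = hamming_capped(read.c_str(), ref.c_str() + o, L, cap);
    if (mm <= cap) best.add(mm, o, strand);
  }
}

static void scan_seeded(const std::string &read, const std::string &ref,
                        const KmerIndex &idx, int cap, int strand, Best &best,
                        std::vector<int> &cand) {
  int L = (int) read.size(), n = (int) ref.size();
  if (L > n) return;
  int chunk = L / (cap + 1);
  cand.clear();
  for (int c = 0; c <= cap; ++c) {
    int s = c * chunk;
    // k-mer prefix of the chunk; a chunk matching exactly implies its prefix does
    uint32_t code = 0;
    bool ok = true;
    for (int j = 0; j < KIDX; ++j) {
      int b = base_code(read[s + j]);
      if (b < 0) { ok = false; break; }
      code = (code << 2) | (uint32_t) b;
    }
    if (!ok) continue;
    const std::vector<int> *hits = idx.lookup(code);
    if (!hits) continue;
    for (size_t h = 0; h < hits->size(); ++h) {
      int o = (*hits)[h] - s;
      if (o >= 0 && o + L <= n) cand.push_back(o);
    }
  }
  std::sort(cand.begin(), cand.end());
  cand.erase(std::unique(cand.begin(), cand.end()), cand.end());
  for (size_t i = 0; i < cand.size(); ++i) {
    int mm = hamming_capped(read.c_str(), ref.c_str() + cand[i], L, cap);
    if (mm <= cap) best.add(mm, cand[i], strand);
  }
}

// [[Rcpp::export(name = ".map_reads_cpp")]]
DataFrame map_reads_cpp(CharacterVector reads, std::string reference,
                        int max_mm = 3, bool strict_multi = false) {
  KmerIndex idx(reference);
  int n = reads.size();
  IntegerVector pos(n), mism(n), n_best(n), n_hits(n);
  CharacterVector strand(n), status(n);
  std::vector<int> cand;
  cand.reserve(64);

  for (int i = 0; i < n; ++i) {
    std::string fwd = as<std::string>(reads[i]);
    int L = (int) fwd.size();
    Best best(max_mm);
    if (L >= 1 && L <= (int) reference.size()) {
      std::string rev(L, 'N');
      for (int j = 0; j < L; ++j) rev[j] = comp_base(fwd[L - 1 - j]);
      bool seeded = (L / (max_mm + 1)) >= KIDX;
      if (seeded) {
        scan_seeded(fwd, reference, idx, max_mm, 0, best, cand);
        scan_seeded(rev, reference, idx, max_mm, 1, best, cand);
      } else {
        scan_all_offsets(fwd, reference, max_mm, 0, best);
        scan_all_offsets(rev, reference, max_mm, 1, best);
      }
    }
    if (best.n_hits == 0) {
      status[i] = "unmapped";
      pos[i] = NA_INTEGER; mism[i] = NA_INTEGER;
      strand[i] = NA_STRING; n_best[i] = 0; n_hits[i] = 0;
    } else {
      bool multi = strict_multi ? (best.n_hits > 1) : (best.n_best > 1);
      status[i] = multi ? "multi" : "unique";
      pos[i] = best.best_pos;
      mism[i] = best.best_mm;
      strand[i] = best.best_strand == 0 ? "+" : "-";
      n_best[i] = best.n_best;
      n_hits[i] = best.n_hits;
    }
  }
  return DataFrame::create(
    _["pos"] = pos, _["strand"] = strand, _["mismatches"] = mism,
    _["status"] = status, _["n_best"] = n_best, _["n_hits"] = n_hits,
    _["stringsAsFactors"] = false);
}
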